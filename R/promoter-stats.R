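#' Extract strand-corrected promoter sequences
#'
#' Pulls the `upstream` bp 5' of each gene's start codon from the genome,
#' reverse-complementing '-'-strand windows so that in every returned
#' sequence the last position is the base adjacent to the start codon.
#' Genes whose window would be clipped by a contig edge are dropped with a
#' warning, so all members have equal length.
#'
#' @param genes annotation data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param upstream promoter length L in bp (default 150).
#' @param label set label carried in the result.
#' @return object of class `promoter_set`: list(label, upstream, members)
#'   where members is a data.frame (gene_id, sequence).
#' @export
extract_promoters <- function(genes, genome, upstream = 150L,
                              label = "promoters") {
  assert_genes(genes)
  validate_genome(genome)
  missing_ctg <- setdiff(unique(genes$contig), names(genome))
  if (length(missing_ctg)) {
    stop("contig(s) absent from genome: ", paste(missing_ctg, collapse = ", "))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  prom <- promoter_windows(genes, upstream, contig_lengths = lens)
  full <- (prom$end - prom$start) == upstream
  if (!any(full)) stop("every promoter window is clipped by a contig edge")
  if (any(!full)) {
    warning(sum(!full), " promoter window(s) clipped at contig edges; dropped")
  }
  prom <- prom[full, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(prom)), function(i) {
    s <- Biostrings::subseq(genome[[prom$contig[i]]],
                            start = prom$start[i] + 1L, end = prom$end[i])
    if (prom$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  structure(list(label = label, upstream = as.integer(upstream),
                 members = data.frame(gene_id = prom$gene_id, sequence = seqs,
                                      stringsAsFactors = FALSE)),
            class = "promoter_set")
}

#' Sample random promoters as a composition background
#'
#' Draws `n` genes uniformly without replacement (excluding `exclude`, by
#' default so the background is uncontaminated by the regulated set) and
#' extracts their promoters.
#'
#' @param genes annotation data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param n number of genes to draw (default 50).
#' @param seed RNG seed for the draw.
#' @param exclude gene ids to exclude from the draw.
#' @param upstream promoter length in bp.
#' @return a `promoter_set` labelled "random".
#' @export
sample_random_promoters <- function(genes, genome, n = 50L, seed = 1L,
                                    exclude = character(), upstream = 150L) {
  assert_genes(genes)
  eligible <- genes[!genes$gene_id %in% exclude, , drop = FALSE]
  # only genes whose window is not clipped by a contig edge, so the sample
  # size is exact
  lens <- setNames(Biostrings::width(genome), names(genome))
  w <- promoter_windows(eligible, upstream, contig_lengths = lens)
  eligible <- eligible[w$end - w$start == upstream, , drop = FALSE]
  if (nrow(eligible) < n) {
    stop("only ", nrow(eligible), " eligible genes for a sample of ", n)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- eligible[sample.int(nrow(eligible), n), , drop = FALSE]
  extract_promoters(pick, genome, upstream, label = "random")
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
# stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

at_fraction_of <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::letterFrequency(x, letters = c("A", "T", "N"))
  denom <- Biostrings::width(x) - counts[, "N"]
  (counts[, "A"] + counts[, "T"]) / denom
}

positional_at_profile <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  colMeans(m == "A" | m == "T")
}

#' Compare AT composition of two promoter sets
#'
#' Computes per-promoter AT fractions, the difference of group means, a
#' two-sided test of that difference, and per-position AT frequency profiles
#' (position 1 is the most upstream base, position L is adjacent to the
#' start codon).
#'
#' @param a,b `promoter_set` objects with equal sequence length.
#' @param test "welch_t" (default), "pooled_t" or "permutation".
#' @param n_perm number of label shuffles for the permutation test.
#' @param seed RNG seed for the permutation test.
#' @return list(mean_at_a, mean_at_b, difference, statistic, p_value,
#'   positional_profile_a, positional_profile_b, test, n_a, n_b).
#' @export
compare_at <- function(a, b, test = c("welch_t", "pooled_t", "permutation"),
                       n_perm = 10000L, seed = 1L) {
  test <- match.arg(test)
  stopifnot(inherits(a, "promoter_set"), inherits(b, "promoter_set"))
  if (nrow(a$members) == 0 || nrow(b$members) == 0) {
    stop("both promoter sets must be nonempty")
  }
  if (a$upstream != b$upstream) {
    stop("promoter sets have different sequence lengths (",
         a$upstream, " vs ", b$upstream, ")")
  }
  at_a <- at_fraction_of(a$members$sequence)
  at_b <- at_fraction_of(b$members$sequence)
  diff_obs <- mean(at_a) - mean(at_b)
  if (test %in% c("welch_t", "pooled_t")) {
    if (sd(at_a) == 0 && sd(at_b) == 0) {
      # degenerate composition (e.g. identical sequences): no test to run
      equal <- isTRUE(all.equal(mean(at_a), mean(at_b)))
      statistic <- if (equal) 0 else Inf * sign(diff_obs)
      p_value <- if (equal) 1 else 0
    } else {
      tt <- t.test(at_a, at_b, var.equal = (test == "pooled_t"))
      statistic <- unname(tt$statistic)
      p_value <- tt$p.value
    }
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pooled <- c(at_a, at_b)
    na <- length(at_a)
    extreme <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      d <- mean(pooled[idx]) - mean(pooled[-idx])
      if (abs(d) >= abs(diff_obs)) extreme <- extreme + 1L
    }
    statistic <- diff_obs
    p_value <- (1 + extreme) / (1 + n_perm)
  }
  list(
    mean_at_a = mean(at_a), mean_at_b = mean(at_b),
    difference = diff_obs, statistic = statistic, p_value = p_value,
    positional_profile_a = positional_at_profile(a$members$sequence),
    positional_profile_b = positional_at_profile(b$members$sequence),
    test = test, n_a = length(at_a), n_b = length(at_b)
  )
}

#' Write positional AT profiles to TSV
#'
#' Positions are indexed -L ... -1 relative to the start codon.
#'
#' @param comparison output of [compare_at()].
#' @param path output TSV.
#' @param labels column labels for the two profiles.
#' @return `path`, invisibly.
#' @export
write_at_profiles <- function(comparison, path,
                              labels = c("set_a", "set_b")) {
  L <- length(comparison$positional_profile_a)
  out <- data.frame(position = seq.int(-L, -1L),
                    a = comparison$positional_profile_a,
                    b = comparison$positional_profile_b)
  names(out)[2:3] <- labels
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
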