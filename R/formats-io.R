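#' Read a genome from FASTA
#'
#' Sequences are uppercased on input and validated to contain only A, C, G, T
#' or N; any other symbol is rejected rather than silently remapped, because
#' downstream AT fractions must be well defined.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by contig id (first whitespace
#'   token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
}

validate_genome <- function(genome) {
  if (length(genome) == 0) stop("FASTA contains no records")
  if (any(names(genome) == "")) stop("FASTA record with empty header")
  dup <- names(genome)[duplicated(names(genome))]
  if (length(dup)) stop("duplicate contig id(s): ", paste(unique(dup), collapse = ", "))
  w <- Biostrings::width(genome)
  if (any(w == 0)) {
    stop("empty sequence for record(s): ",
         paste(names(genome)[w == 0], collapse = ", "))
  }
  ok <- Biostrings::letterFrequency(genome, letters = "ACGTN", OR = "|")[, 1]
  bad <- which(ok != w)
  if (length(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(names(genome)[bad], collapse = ", "))
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output file.
#' @param width line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features only and converts the 1-based inclusive GFF3
#' coordinates to the package-wide 0-based half-open convention
#' (start - 1, end). Strand must be '+' or '-'.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default "gene").
#' @return data.frame with columns gene_id, contig, start, end, strand.
#' @export
read_gff3 <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.frame(gr)
  df <- df[!is.na(df$type) & as.character(df$type) == feature, , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no '", feature, "' features in ", path, "; empty annotation")
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- if ("ID" %in% names(df)) df$ID else rep(NA_character_, nrow(df))
  if (any(is.na(ids) | ids == "")) {
    stop("gene feature without an ID attribute in ", path)
  }
  strand <- as.character(df$strand)
  if (!all(strand %in% c("+", "-"))) {
    stop("gene with unknown strand in ", path,
         " (strand must be '+' or '-')")
  }
  genes <- data.frame(
    gene_id = as.character(ids),
    contig  = as.character(df$seqnames),
    start   = df$start - 1L,
    end     = df$end,
    strand  = strand,
    stringsAsFactors = FALSE
  )
  assert_genes(genes)
  genes[order(genes$contig, genes$start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' Converts the internal 0-based half-open intervals back to 1-based
#' inclusive GFF3 coordinates.
#'
#' @param genes annotation data.frame (gene_id, contig, start, end, strand).
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "napregulon") {
  assert_genes(genes)
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$contig, source, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read ChIP binding sites from BED
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Site midpoints are `floor((start + end) / 2)`. Ids come from column 4 when
#' present, otherwise `peak_0001`-style ids are assigned in file order.
#'
#' @param path BED3+ file.
#' @return data.frame with columns peak_id, contig, start, end, midpoint,
#'   score (NA when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0) {
    warning("empty BED file: ", path)
    return(data.frame(peak_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      midpoint = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  start <- suppressWarnings(as.integer(bed[[2]]))
  end <- suppressWarnings(as.integer(bed[[3]]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer BED coordinates at line ",
         which(is.na(start) | is.na(end))[1], " of ", path)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED interval with start >= end at line ", bad[1], " of ", path)
  }
  ids <- if (ncol(bed) >= 4) bed[[4]] else sprintf("peak_%04d", seq_len(nrow(bed)))
  score <- if (ncol(bed) >= 5) suppressWarnings(as.numeric(bed[[5]])) else
    rep(NA_real_, nrow(bed))
  data.frame(
    peak_id = ids, contig = bed[[1]], start = start, end = end,
    midpoint = (start + end) %/% 2L, score = score,
    stringsAsFactors = FALSE
  )
}

#' Write binding sites to BED
#'
#' @param peaks peak data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  assert_peaks(peaks)
  score <- if ("score" %in% names(peaks)) peaks$score else NA_real_
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$contig, peaks$start, peaks$end,
                   peaks$peak_id,
                   ifelse(is.na(score), ".", format(score, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Consumes the per-gene output of an upstream DE fit (e.g. a voom/limma
#' contrast exported as TSV). The contract is a plain header TSV; column
#' names can be remapped for real exports via `col_map`.
#'
#' @param path TSV with header columns gene_id, log2fc, adj_p.
#' @param condition condition label attached to every record.
#' @param col_map named character vector mapping the required names to the
#'   file's column names, e.g. `c(log2fc = "logFC", adj_p = "adj.P.Val")`.
#' @return data.frame with columns gene_id, log2fc, adj_p, condition.
#' @export
read_de_table <- function(path, condition, col_map = NULL) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  de <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (std in names(col_map)) {
    if (!col_map[[std]] %in% names(de)) {
      stop("mapped column '", col_map[[std]], "' absent from ", path)
    }
    names(de)[names(de) == col_map[[std]]] <- std
  }
  needed <- c("gene_id", "log2fc", "adj_p")
  if (!all(needed %in% names(de))) {
    stop("DE table must have columns ", paste(needed, collapse = ", "),
         " (missing: ", paste(setdiff(needed, names(de)), collapse = ", "), ")")
  }
  for (col in c("log2fc", "adj_p")) {
    if (!is.numeric(de[[col]])) {
      stop("non-numeric values in DE column '", col, "' of ", path)
    }
  }
  if (any(de$adj_p < 0 | de$adj_p > 1, na.rm = TRUE) || anyNA(de$adj_p)) {
    stop("adj_p outside [0, 1] in ", path)
  }
  key <- paste(de$gene_id, condition)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, condition) record in ", path)
  }
  data.frame(gene_id = de$gene_id, log2fc = de$log2fc, adj_p = de$adj_p,
             condition = condition, stringsAsFactors = FALSE)
}

#' Write a differential-expression table
#'
#' @param de DE data.frame (gene_id, log2fc, adj_p, ...).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("gene_id", "log2fc", "adj_p")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Flat `key: value` record of the parameters and seeds of a run, so that any
#' output directory is self-describing.
#'
#' @param params named list of scalar parameters.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  stopifnot(!is.null(names(params)), all(names(params) != ""))
  vals <- vapply(params, function(v) paste(format(v, trim = TRUE),
                                           collapse = ","), character(1))
  writeLines(paste0(names(params), ": ", vals), path)
  invisible(path)
}
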