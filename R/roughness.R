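#' Ra: arithmetic mean deviation of a roughness profile
#'
#' For a line of height samples z, Ra = mean(|z - mean(z)|). By default the
#' reference line is the profile mean; `detrend = TRUE` removes a fitted
#' linear trend first (useful for tilted scans).
#'
#' @param heights numeric vector of height samples (nm), length >= 2.
#' @param detrend remove a least-squares linear trend before computing Ra.
#' @return Ra in the units of `heights`.
#' @export
compute_ra <- function(heights, detrend = FALSE) {
  if (length(heights) < 2) stop("a roughness line needs at least 2 samples")
  if (detrend) {
    i <- seq_along(heights)
    heights <- stats::residuals(stats::lm(heights ~ i))
  }
  mean(abs(heights - mean(heights)))
}

#' Per-cell roughness from multiple scan lines
#'
#' Each cell is scanned along several (typically 3 or 4) 500-nm lines; the
#' cell's Ra is the unweighted mean of the per-line Ra values.
#'
#' @param profiles data.frame with columns cell_id, line_id, height_nm
#'   (sample order within a line follows row order, or sample_index when
#'   present).
#' @param detrend passed to [compute_ra()].
#' @return data.frame with columns cell_id, n_lines, ra.
#' @export
cell_ra <- function(profiles, detrend = FALSE) {
  needed <- c("cell_id", "line_id", "height_nm")
  if (!all(needed %in% names(profiles))) {
    stop("profiles must have columns ", paste(needed, collapse = ", "))
  }
  if ("sample_index" %in% names(profiles)) {
    profiles <- profiles[order(profiles$cell_id, profiles$line_id,
                               profiles$sample_index), , drop = FALSE]
  }
  per_line <- lapply(split(profiles,
                           paste(profiles$cell_id, profiles$line_id, sep = "\r")),
                     function(d) data.frame(cell_id = d$cell_id[1],
                                            ra = compute_ra(d$height_nm, detrend),
                                            stringsAsFactors = FALSE))
  per_line <- do.call(rbind, per_line)
  out <- do.call(rbind, lapply(split(per_line, per_line$cell_id), function(d) {
    data.frame(cell_id = d$cell_id[1], n_lines = nrow(d), ra = mean(d$ra),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Read AFM line profiles from TSV
#'
#' @param path TSV with header columns cell_id, line_id, sample_index,
#'   height_nm.
#' @return data.frame of profiles.
#' @export
read_roughness_tsv <- function(path) {
  if (!file.exists(path)) stop("roughness TSV not found: ", path)
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("cell_id", "line_id", "sample_index", "height_nm")
  if (!all(needed %in% names(d))) {
    stop("roughness TSV must have columns ", paste(needed, collapse = ", "))
  }
  if (!is.numeric(d$height_nm)) stop("non-numeric height_nm in ", path)
  d
}

#' Two-group comparison of per-cell roughness
#'
#' Two-sided two-sample t-test with pooled standard deviation on the per-cell
#' Ra values (df = n_a + n_b - 2). When both groups have zero variance and
#' equal means, p = 1 by convention.
#'
#' @param a,b data.frames from [cell_ra()] (or any frame with an `ra`
#'   column), one per strain/group.
#' @return list(mean_a, sd_a, n_a, mean_b, sd_b, n_b, t_statistic, df,
#'   p_value).
#' @export
compare_roughness_groups <- function(a, b) {
  ra_a <- if (is.data.frame(a)) a$ra else a
  ra_b <- if (is.data.frame(b)) b$ra else b
  if (length(ra_a) < 2 || length(ra_b) < 2) {
    stop("each group needs at least 2 cells")
  }
  base <- list(mean_a = mean(ra_a), sd_a = sd(ra_a), n_a = length(ra_a),
               mean_b = mean(ra_b), sd_b = sd(ra_b), n_b = length(ra_b))
  if (sd(ra_a) == 0 && sd(ra_b) == 0) {
    equal <- isTRUE(all.equal(mean(ra_a), mean(ra_b)))
    return(c(base, list(t_statistic = if (equal) 0 else Inf * sign(mean(ra_a) - mean(ra_b)),
                        df = length(ra_a) + length(ra_b) - 2L,
                        p_value = if (equal) 1 else 0)))
  }
  tt <- t.test(ra_a, ra_b, var.equal = TRUE)
  c(base, list(t_statistic = unname(tt$statistic),
               df = as.integer(unname(tt$parameter)),
               p_value = tt$p.value))
}
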