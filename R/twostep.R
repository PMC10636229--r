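#' Step-1 screening p-value from the D|G and G|E components
#'
#' The screening statistic combines the marginal genetic association and the
#' combined-sample gene-environment correlation: the two 1-df chi-squares are
#' summed and referred to a chi-square with 2 df. Both components are
#' asymptotically independent of the step-2 interaction test under the null,
#' which is what allows the screen to be used without spending alpha.
#'
#' @param chi2_dg chi-square of the marginal D|G test (1 df).
#' @param chi2_ge chi-square of the combined-sample G|E test (1 df).
#' @return screening p-value; NA if either component is missing.
#' @export
screening_pvalue <- function(chi2_dg, chi2_ge) {
  p <- stats::pchisq(chi2_dg + chi2_ge, df = 2, lower.tail = FALSE)
  p[is.na(chi2_dg) | is.na(chi2_ge)] <- NA_real_
  p
}

#' Rank-dependent alpha thresholds by bin doubling
#'
#' Implements weighted hypothesis testing: after ranking variants by the
#' screening p-value, the first `bin0_size` ranks form bin 1, the next
#' `2 * bin0_size` bin 2, then `4 * bin0_size`, and so on (the last bin is
#' truncated to the remaining variants). Bin `b` receives `alpha_total *
#' 2^-b`, split equally over its members, so highly ranked variants get
#' lenient per-test thresholds while the total alpha spent is bounded by
#' `alpha_total * (1 - 2^-n_bins) <= alpha_total`. The truncated last bin
#' keeps the threshold computed with its truncated size (slightly
#' conservative); `redistribute = TRUE` instead spreads all remaining alpha
#' over the last bin.
#'
#' @param m number of ranked variants.
#' @param alpha_total genome-wide alpha for the interaction test (default 0.05).
#' @param bin0_size size of the first (most lenient) bin (default 5).
#' @param redistribute give the final truncated bin the entire unspent alpha
#'   tail (default FALSE).
#' @return data.frame with one row per rank: `rank`, `bin_index`,
#'   `alpha_threshold`. Thresholds depend only on `(m, alpha_total,
#'   bin0_size)`, never on observed p-values.
#' @export
allocate_weighted_alpha <- function(m, alpha_total = 0.05, bin0_size = 5L,
                                    redistribute = FALSE) {
  stopifnot(m >= 1, bin0_size >= 1, alpha_total > 0, alpha_total < 1)
  sizes <- integer(0)
  total <- 0L
  b <- 0L
  while (total < m) {
    b <- b + 1L
    sz <- min(bin0_size * 2L^(b - 1L), m - total)
    sizes <- c(sizes, sz)
    total <- total + sz
  }
  n_bins <- length(sizes)
  alpha_bin <- alpha_total * 2^(-seq_len(n_bins))
  if (isTRUE(redistribute) && n_bins >= 1L) {
    alpha_bin[n_bins] <- alpha_total * 2^(-(n_bins - 1L))
  }
  thr_bin <- alpha_bin / sizes
  # a heavily truncated final bin could otherwise get a more lenient
  # threshold than its predecessor; cap to keep thresholds non-increasing
  # in rank (capping only lowers the total alpha spent)
  thr_bin <- cummin(thr_bin)
  data.frame(rank = seq_len(m),
             bin_index = rep(seq_len(n_bins), sizes),
             alpha_threshold = rep(thr_bin, sizes))
}

#' Run the two-step weighted hypothesis testing procedure
#'
#' Step 1 ranks variants by the screening p-value (ascending; ties broken by
#' genomic order). Step 2 compares each variant's interaction p-value with
#' the rank-dependent threshold from [allocate_weighted_alpha()]. Variants
#' missing either the screening components or the interaction p-value are
#' excluded from ranking and logged.
#'
#' @param scan output of [gxe_scan()] (needs `chi2_dg`, `chi2_ge`, `p_gxe`,
#'   `chr`, `pos`, `rsid`).
#' @param alpha_total genome-wide alpha (default 0.05).
#' @param bin0_size first-bin size (default 5).
#' @param redistribute see [allocate_weighted_alpha()].
#' @return data.frame sorted by rank: variant identifiers, `p_screen`,
#'   `rank`, `bin_index`, `alpha_threshold`, `p_gxe`, `significant`.
#'   Attributes `alpha_total`, `bin0_size`, `total_alpha_spent` and
#'   `n_excluded` record the procedure-level quantities.
#' @export
run_two_step <- function(scan, alpha_total = 0.05, bin0_size = 5L,
                         redistribute = FALSE) {
  scan <- as.data.frame(scan)
  p_screen <- screening_pvalue(scan$chi2_dg, scan$chi2_ge)
  usable <- !is.na(p_screen) & !is.na(scan$p_gxe)
  if (!any(usable)) stop("no variant has complete screening and interaction statistics")
  if (any(!usable)) {
    gxewas_log("twostep", sum(!usable), " variant(s) excluded from ranking (incomplete statistics)")
  }
  df <- data.frame(chr = scan$chr, pos = scan$pos, rsid = scan$rsid,
                   p_screen = p_screen, p_gxe = scan$p_gxe,
                   stringsAsFactors = FALSE)[usable, , drop = FALSE]
  ord <- order(df$p_screen, df$chr, df$pos)
  df <- df[ord, , drop = FALSE]
  alloc <- allocate_weighted_alpha(nrow(df), alpha_total, bin0_size, redistribute)
  df$rank <- alloc$rank
  df$bin_index <- alloc$bin_index
  df$alpha_threshold <- alloc$alpha_threshold
  df$significant <- df$p_gxe < df$alpha_threshold
  rownames(df) <- NULL
  df <- df[, c("chr", "pos", "rsid", "p_screen", "rank", "bin_index",
               "alpha_threshold", "p_gxe", "significant")]
  attr(df, "alpha_total") <- alpha_total
  attr(df, "bin0_size") <- as.integer(bin0_size)
  attr(df, "total_alpha_spent") <- sum(tapply(df$alpha_threshold, df$bin_index, max) *
                                         tabulate(df$bin_index))
  attr(df, "n_excluded") <- sum(!usable)
  df
}
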