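# Tissue-specificity proxies: expression specificity from a TPM matrix and
# peak specificity from an ATAC presence matrix. These proxy the trait
# specificity of genes (Psi_G) and of regulatory variants (Psi_V) when
# a trait maps predominantly to one tissue.

#' Expression specificity scores for a focal tissue
#'
#' A gene is considered expressed when its focal-tissue TPM strictly
#' exceeds the threshold; its specificity score is the focal-tissue TPM
#' divided by the sum of TPM across all tissues (focal included).
#' Unexpressed genes carry no score and are excluded from downstream bins.
#'
#' @param tpm numeric matrix of nonnegative expression values, genes x
#'   tissues, with dimnames.
#' @param focal focal tissue name or column index; defaults to the
#'   matrix's `focal_tissue` attribute.
#' @param tpm_threshold expression threshold (default 10, strict).
#' @return data.frame with `id`, `tpm_focal`, `expressed`, `score` (NA for
#'   unexpressed genes).
#' @export
expression_specificity_scores <- function(tpm, focal = NULL,
                                          tpm_threshold = 10) {
  if (is.null(focal)) focal <- attr(tpm, "focal_tissue")
  if (is.character(focal) && !(focal %in% colnames(tpm))) {
    stop("focal tissue not present in matrix")
  }
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  if (ncol(tpm) < 2L) stop("need at least 2 tissues")
  expressed <- tpm[, focal] > tpm_threshold
  score <- ifelse(expressed, tpm[, focal] / rowSums(tpm), NA_real_)
  data.frame(id = rownames(tpm) %||% sprintf("gene%05d", seq_len(nrow(tpm))),
             tpm_focal = tpm[, focal], expressed = expressed, score = score,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled quintile assignment of specificity scores
#'
#' Quintile breakpoints are computed once on the pooled score distribution
#' (typically across several trait-tissue pairs) and every scored entity
#' is assigned its pooled quintile. Scores exactly at a breakpoint go to
#' the lower bin, so a degenerate pool of identical scores lands entirely
#' in bin 1.
#'
#' @param profiles data.frame with a `score` column (NA scores are left
#'   unbinned); e.g. one or several row-bound outputs of
#'   [expression_specificity_scores()].
#' @return `profiles` with an integer `bin` column (1 = least specific,
#'   5 = most specific) appended.
#' @export
pooled_quintiles <- function(profiles) {
  sc <- profiles$score
  pool <- sc[!is.na(sc)]
  if (length(pool) < 5L) stop("need at least 5 scored entities to pool quintiles")
  brk <- stats::quantile(pool, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  bin <- rep(NA_integer_, length(sc))
  ok <- !is.na(sc)
  b <- rep(1L, sum(ok))
  for (k in seq_along(brk)) b <- b + (sc[ok] > brk[k])
  bin[ok] <- b
  profiles$bin <- bin
  profiles
}

#' ATAC peak tissue-sharing and intensity specificity
#'
#' A peak is present in a tissue when its presence fraction strictly
#' exceeds the threshold. Only peaks present in the focal tissue are
#' profiled. Sharing is the number of tissues in which a profiled peak is
#' present, binned into the classes 1-2, 3-8, 9-15, 16-18 and all tissues
#' (edges designed for a 19-tissue compendium). Peak intensity is the
#' focal-tissue presence fraction; intensity bins are sized to match the
#' sharing-bin sizes, with the highest intensities paired with the
#' most-specific-sized bin.
#'
#' @param peaks numeric matrix of presence fractions in `[0, 1]`, peaks x
#'   tissues, with dimnames.
#' @param focal focal tissue name or column index; defaults to the
#'   matrix's `focal_tissue` attribute.
#' @param presence_threshold presence cutoff (default 0.05, strict).
#' @return data.frame of profiled peaks with `id`, `sharing`,
#'   `sharing_bin` (factor), `intensity`, `intensity_bin`.
#' @export
atac_peak_specificity <- function(peaks, focal = NULL,
                                  presence_threshold = 0.05) {
  if (is.null(focal)) focal <- attr(peaks, "focal_tissue")
  if (is.character(focal) && !(focal %in% colnames(peaks))) {
    stop("focal tissue not present in matrix")
  }
  if (any(peaks < 0 | peaks > 1)) stop("presence fractions must be in [0, 1]")
  present <- peaks > presence_threshold
  profiled <- which(present[, focal])
  n_tis <- ncol(peaks)
  sharing <- rowSums(present)[profiled]
  labels <- c("1-2", "3-8", "9-15", "16-18", as.character(n_tis))
  sharing_bin <- cut(sharing, breaks = c(0, 2, 8, 15, n_tis - 1L, n_tis),
                     labels = labels)
  intensity <- peaks[profiled, focal]
  ids <- rownames(peaks) %||% sprintf("peak%05d", seq_len(nrow(peaks)))
  out <- data.frame(id = ids[profiled], sharing = sharing,
                    sharing_bin = sharing_bin, intensity = intensity,
                    row.names = NULL, stringsAsFactors = FALSE)
  sizes <- as.integer(table(sharing_bin))
  ord <- order(-out$intensity, out$id)
  ibin <- integer(nrow(out))
  ibin[ord] <- rep(seq_along(sizes), times = sizes)
  out$intensity_bin <- factor(labels[ibin], levels = labels)
  out
}
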