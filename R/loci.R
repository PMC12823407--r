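# GWAS locus grouping, ranking, power-matched selection and concordance
# with burden-test hits. Coordinates are 0-based half-open throughout;
# tie-breaking is (P, chrom, pos) lexicographic so ranks are reproducible
# bit for bit.

validate_hits <- function(hits) {
  need <- c("chrom", "pos", "log10p")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "))
  }
  if (any(hits$log10p > 0)) stop("log10p must be <= 0")
  if (any(hits$pos < 0)) stop("pos must be >= 0")
  if (anyDuplicated(hits[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in hits")
  }
  hits
}

#' Group approximately independent GWAS hits into loci
#'
#' Seeds a locus at the most significant unassigned hit, absorbs every
#' unassigned hit within `window_bp` of any member, and iterates the
#' expansion to a fixed point before seeding the next locus. Because
#' membership is a transitive closure, the resulting partition does not
#' depend on the input row order. The locus span is the member range
#' padded by `span_pad` on each side (clipped at 0), half-open.
#'
#' @param hits data.frame with columns `chrom`, `pos` (0-based), `log10p`
#'   and optionally `beta`, `maf`.
#' @param window_bp inter-hit grouping distance (default 1 Mb).
#' @param span_pad padding added to the member range for the locus span and
#'   gene assignment (default `window_bp / 2`, i.e. a 1 Mb window around an
#'   isolated hit).
#' @return an object of class `"locus_set"`: list with `loci` (data.frame:
#'   `locus_id`, `chrom`, `start`, `end`, `n_hits`, `min_log10p`),
#'   `members` (list of row indices into `hits` per locus), `hits`,
#'   `window_bp`, `span_pad`. Loci are ordered by discovery (most
#'   significant seed first); see [rank_loci()].
#' @export
group_hits_into_loci <- function(hits, window_bp = 1e6,
                                 span_pad = window_bp / 2) {
  hits <- validate_hits(hits)
  n <- nrow(hits)
  loci <- list(); members <- list()
  if (n > 0L) {
    ord <- order(hits$log10p, hits$chrom, hits$pos)
    assigned <- logical(n)
    for (i in ord) {
      if (assigned[i]) next
      same <- which(hits$chrom == hits$chrom[i] & !assigned)
      lo <- hi <- hits$pos[i]
      member <- i; assigned[i] <- TRUE
      repeat {
        cand <- same[!assigned[same] &
                     hits$pos[same] >= lo - window_bp &
                     hits$pos[same] <= hi + window_bp]
        if (length(cand) == 0L) break
        assigned[cand] <- TRUE
        member <- c(member, cand)
        lo <- min(lo, hits$pos[cand]); hi <- max(hi, hits$pos[cand])
      }
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = hits$chrom[i], start = max(0, lo - span_pad),
        end = hi + span_pad + 1, n_hits = length(member),
        min_log10p = min(hits$log10p[member]))
      members[[length(members) + 1L]] <- sort(member)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_hits = integer(), min_log10p = numeric())
  loci$locus_id <- seq_len(nrow(loci))
  structure(list(loci = loci[, c("locus_id", "chrom", "start", "end",
                                 "n_hits", "min_log10p")],
                 members = members, hits = hits,
                 window_bp = window_bp, span_pad = span_pad),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("locus_set: %d loci from %d hits (window %g bp, pad %g bp)\n",
              nrow(x$loci), nrow(x$hits), x$window_bp, x$span_pad))
  invisible(x)
}

#' Assign overlapping genes to loci
#'
#' A gene belongs to a locus when its interval intersects the locus span;
#' both are 0-based half-open, so a gene ending exactly where a span starts
#' does not overlap. A gene may belong to several loci.
#'
#' @param locus_set a `"locus_set"`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return the `locus_set` with a `genes` element added: a list of
#'   gene-id character vectors, one per locus.
#' @export
assign_genes <- function(locus_set, genes) {
  stopifnot(inherits(locus_set, "locus_set"))
  if (any(genes$start >= genes$end)) stop("malformed gene intervals")
  loci <- locus_set$loci
  gene_lists <- rep(list(character(0)), nrow(loci))
  if (nrow(loci) > 0L && nrow(genes) > 0L) {
    # half-open [start, end) converted to 1-based closed for IRanges
    gr_loci <- GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$start + 1, loci$end))
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_loci, gr_genes))
    for (j in seq_len(nrow(loci))) {
      gene_lists[[j]] <- sort(genes$gene_id[
        S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == j]])
    }
  }
  locus_set$genes <- gene_lists
  locus_set$gene_table <- genes
  locus_set
}

#' Rank loci by significance or by largest significant effect
#'
#' @param locus_set a `"locus_set"`.
#' @param mode `"min_p"` ranks by the smallest P value among member hits;
#'   `"max_abs_beta_significant"` ranks by the largest absolute effect size
#'   among genome-wide significant member hits (loci with no significant
#'   member are excluded with a note).
#' @param sig_threshold significance threshold for the effect mode
#'   (default 5e-8).
#' @return the `locus_set` with loci (and parallel `members`/`genes`)
#'   reordered by rank and a `rank` column added; excluded locus ids, if
#'   any, are recorded in the attribute `"excluded"` of the `loci` table.
#' @export
rank_loci <- function(locus_set, mode = c("min_p", "max_abs_beta_significant"),
                      sig_threshold = 5e-8) {
  stopifnot(inherits(locus_set, "locus_set"))
  mode <- match.arg(mode)
  loci <- locus_set$loci
  keep <- seq_len(nrow(loci))
  if (mode == "min_p") {
    ord <- order(loci$min_log10p, loci$chrom, loci$start)
  } else {
    if (is.null(locus_set$hits$beta)) stop("effect mode requires a beta column")
    log_thr <- log10(sig_threshold)
    key <- vapply(locus_set$members, function(m) {
      sig <- m[locus_set$hits$log10p[m] < log_thr]
      if (length(sig) == 0L) NA_real_ else max(abs(locus_set$hits$beta[sig]))
    }, numeric(1))
    keep <- which(!is.na(key))
    if (length(keep) < nrow(loci)) {
      message(sprintf("excluding %d locus/loci with no significant member hit",
                      nrow(loci) - length(keep)))
    }
    ord <- keep[order(-key[keep], loci$chrom[keep], loci$start[keep])]
  }
  excluded <- setdiff(loci$locus_id, loci$locus_id[ord])
  locus_set$loci <- loci[ord, , drop = FALSE]
  locus_set$loci$rank <- seq_along(ord)
  rownames(locus_set$loci) <- NULL
  locus_set$members <- locus_set$members[ord]
  if (!is.null(locus_set$genes)) locus_set$genes <- locus_set$genes[ord]
  attr(locus_set$loci, "excluded") <- excluded
  locus_set
}

#' Select top loci power-matched to the burden test
#'
#' Walks ranked loci from the top, matching the gene-discovery power of the
#' burden test: the target count is the number of burden-significant genes;
#' from each locus, all burden-significant member genes are selected, or,
#' if none, the single member gene with the smallest burden P value.
#' Selection stops once the number of distinct selected genes reaches the
#' target.
#'
#' @param locus_set a ranked `"locus_set"` with genes assigned.
#' @param burden data.frame with `gene_id` and `log10p` covering the gene
#'   universe of the loci.
#' @param burden_threshold burden significance threshold (default 2.7e-6,
#'   the Bonferroni correction of 0.05 for roughly 18,500 genes).
#' @return list with `locus_ids` (selected loci, in rank order), `genes`
#'   (selected gene ids) and `target`.
#' @export
select_power_matched_top_loci <- function(locus_set, burden,
                                          burden_threshold = 2.7e-6) {
  stopifnot(inherits(locus_set, "locus_set"))
  if (is.null(locus_set$genes)) stop("assign_genes() must be run first")
  if (is.null(locus_set$loci$rank)) stop("rank_loci() must be run first")
  log_thr <- log10(burden_threshold)
  sig_genes <- burden$gene_id[burden$log10p < log_thr]
  target <- length(sig_genes)
  selected <- character(0); locus_ids <- integer(0)
  if (target > 0L) {
    bp <- stats::setNames(burden$log10p, burden$gene_id)
    for (j in seq_len(nrow(locus_set$loci))) {
      g <- locus_set$genes[[j]]
      if (length(g) == 0L) next
      sig <- g[g %in% sig_genes]
      take <- if (length(sig) > 0L) sig else {
        p <- bp[g]
        g[order(p, g)][1L]
      }
      selected <- union(selected, take)
      locus_ids <- c(locus_ids, locus_set$loci$locus_id[j])
      if (length(selected) >= target) break
    }
  }
  list(locus_ids = locus_ids, genes = selected, target = target)
}

#' Overlap between burden-significant genes and GWAS loci
#'
#' @param burden data.frame with `gene_id` and `log10p`.
#' @param locus_set a ranked `"locus_set"` with genes assigned.
#' @param top optional result of [select_power_matched_top_loci()]; when
#'   supplied, the fraction of burden genes inside the power-matched top
#'   loci is also reported.
#' @param burden_threshold burden significance threshold.
#' @return list with `frac_in_any_locus`, `frac_in_top_loci` (NA without
#'   `top`), and `pairs`, a data.frame pairing each burden-significant gene
#'   (ordered by burden P) with the best rank of a containing locus (NA if
#'   outside all loci).
#' @export
burden_gwas_overlap <- function(burden, locus_set, top = NULL,
                                burden_threshold = 2.7e-6) {
  stopifnot(inherits(locus_set, "locus_set"))
  if (is.null(locus_set$genes)) stop("assign_genes() must be run first")
  log_thr <- log10(burden_threshold)
  sig <- burden[burden$log10p < log_thr, , drop = FALSE]
  sig <- sig[order(sig$log10p, sig$gene_id), , drop = FALSE]
  rank_of <- rep(NA_integer_, nrow(sig))
  top_flag <- rep(FALSE, nrow(sig))
  top_loci <- if (is.null(top)) integer(0) else top$locus_ids
  for (j in seq_len(nrow(locus_set$loci))) {
    g <- locus_set$genes[[j]]
    inside <- sig$gene_id %in% g
    r <- locus_set$loci$rank[j]
    upd <- inside & (is.na(rank_of) | rank_of > r)
    rank_of[upd] <- r
    if (locus_set$loci$locus_id[j] %in% top_loci) {
      top_flag <- top_flag | inside
    }
  }
  pairs <- data.frame(gene_id = sig$gene_id, burden_rank = seq_len(nrow(sig)),
                      burden_log10p = sig$log10p, locus_rank = rank_of)
  list(frac_in_any_locus = if (nrow(sig)) mean(!is.na(rank_of)) else NA_real_,
       frac_in_top_loci = if (is.null(top)) NA_real_ else
         if (nrow(sig)) mean(top_flag) else NA_real_,
       pairs = pairs)
}

#' Compare GWAS and burden significance within LD blocks
#'
#' For each block, records the minimum GWAS P among hits inside it and the
#' minimum burden P among genes overlapping it. Blocks whose burden
#' minimizer gene also minimizes another block (one gene spanning a block
#' boundary) are flagged dropped, conservatively.
#'
#' @param blocks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); blocks must not overlap.
#' @param hits data.frame with `chrom`, `pos`, `log10p`.
#' @param burden data.frame with `gene_id`, `log10p`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return a data.frame: block coordinates, `min_gwas_log10p`,
#'   `min_burden_log10p`, `min_burden_gene`, `dropped`.
#' @export
ld_block_compare <- function(blocks, hits, burden, genes) {
  for (cc in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == cc, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stop("LD blocks overlap on ", cc)
    }
  }
  bp <- stats::setNames(burden$log10p, burden$gene_id)
  n <- nrow(blocks)
  min_gwas <- min_burden <- rep(NA_real_, n)
  min_gene <- rep(NA_character_, n)
  gr_blocks <- GenomicRanges::GRanges(
    blocks$chrom, IRanges::IRanges(blocks$start + 1, blocks$end))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_blocks, gr_genes))
  for (j in seq_len(n)) {
    inb <- hits$chrom == blocks$chrom[j] & hits$pos >= blocks$start[j] &
      hits$pos < blocks$end[j]
    if (any(inb)) min_gwas[j] <- min(hits$log10p[inb])
    g <- genes$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == j]]
    g <- g[g %in% names(bp)]
    if (length(g) > 0L) {
      p <- bp[g]
      best <- g[order(p, g)][1L]
      min_burden[j] <- bp[[best]]
      min_gene[j] <- best
    }
  }
  dup_genes <- unique(min_gene[duplicated(min_gene) & !is.na(min_gene)])
  out <- blocks
  out$min_gwas_log10p <- min_gwas
  out$min_burden_log10p <- min_burden
  out$min_burden_gene <- min_gene
  out$dropped <- !is.na(min_gene) & min_gene %in% dup_genes
  out
}

#' Filter hits by a MAF threshold
#'
#' Keeps hits with MAF less than or equal to the threshold (inclusive);
#' a threshold of 0.5 keeps all hits.
#'
#' @param hits data.frame with a `maf` column.
#' @param maf_threshold threshold in `(0, 0.5]`.
#' @return the filtered hits.
#' @export
filter_hits_by_maf <- function(hits, maf_threshold) {
  stopifnot_scalar(maf_threshold, "maf_threshold")
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    stop("maf_threshold must be in (0, 0.5]")
  }
  hits[hits$maf <= maf_threshold, , drop = FALSE]
}
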