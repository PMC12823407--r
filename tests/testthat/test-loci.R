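test_that("locus spans follow the padding rule", {
  hits <- data.frame(chrom = "chr1", pos = 1e7, log10p = -20)
  ls <- group_hits_into_loci(hits)
  expect_equal(ls$loci$start, 9.5e6)
  expect_equal(ls$loci$end, 10.5e6 + 1)
  expect_equal(ls$loci$n_hits, 1L)
  empty <- group_hits_into_loci(hits[0, ])
  expect_equal(nrow(empty$loci), 0L)
  expect_error(group_hits_into_loci(rbind(hits, hits)), "duplicate")
})

test_that("grouping separates distant hits and closes transitive chains", {
  hits <- data.frame(chrom = "chr1", pos = c(1.0e6, 1.5e6, 3.0e6),
                     log10p = c(-20, -10, -9))
  ls <- group_hits_into_loci(hits)
  expect_equal(nrow(ls$loci), 2L)
  expect_equal(sort(ls$members[[1]]), c(1L, 2L))
  expect_equal(ls$members[[2]], 3L)

  chain <- data.frame(chrom = "chr1", pos = c(0, 0.9e6, 1.8e6),
                      log10p = c(-30, -8, -12))
  ls2 <- group_hits_into_loci(chain)
  expect_equal(nrow(ls2$loci), 1L)
  expect_equal(sort(ls2$members[[1]]), 1:3)
})

test_that("locus membership matches the closure oracle and ignores input order", {
  set.seed(7)
  for (rep in 1:40) {
    hits <- random_hits(sample(3:25, 1), n_chrom = 2, span = 8e6)
    ls <- group_hits_into_loci(hits)
    got <- lapply(ls$members, sort)
    want <- oracle_group_loci(hits)
    expect_identical(got[order(sapply(got, min))],
                     want[order(sapply(want, min))])
    # shuffling input rows leaves the partition unchanged
    perm <- sample(nrow(hits))
    ls_sh <- group_hits_into_loci(hits[perm, ])
    got_sh <- lapply(ls_sh$members, function(m) sort(perm[m]))
    expect_identical(got_sh[order(sapply(got_sh, min))],
                     want[order(sapply(want, min))])
    # no two loci on a chromosome have member hits within the window
    for (i in seq_along(got)) for (j in seq_along(got)) {
      if (i >= j) next
      hi <- hits[got[[i]], ]; hj <- hits[got[[j]], ]
      if (hi$chrom[1] != hj$chrom[1]) next
      expect_gt(min(abs(outer(hi$pos, hj$pos, "-"))), 1e6)
    }
  }
})

test_that("gene assignment honours half-open interval overlap", {
  hits <- data.frame(chrom = "chr1", pos = 2e6, log10p = -20)
  ls <- group_hits_into_loci(hits) # span [1.5e6, 2.5e6 + 1)
  genes <- data.frame(
    gene_id = c("inside", "touch_left", "overlap_right", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1.6e6, 1.0e6, 2.4e6, 1.6e6),
    end = c(1.7e6, 1.5e6, 3.0e6, 1.7e6))
  ls <- assign_genes(ls, genes)
  expect_setequal(ls$genes[[1]], c("inside", "overlap_right"))

  set.seed(8)
  for (rep in 1:20) {
    hits_r <- random_hits(8, span = 6e6)
    ls_r <- group_hits_into_loci(hits_r)
    n_g <- 30
    gstart <- sample.int(7e6, n_g)
    genes_r <- data.frame(gene_id = sprintf("g%02d", seq_len(n_g)),
                          chrom = paste0("chr", sample.int(2, n_g, TRUE)),
                          start = gstart, end = gstart + sample.int(2e5, n_g))
    ls_r <- assign_genes(ls_r, genes_r)
    for (j in seq_len(nrow(ls_r$loci))) {
      manual <- genes_r$gene_id[genes_r$chrom == ls_r$loci$chrom[j] &
                                genes_r$start < ls_r$loci$end[j] &
                                genes_r$end > ls_r$loci$start[j]]
      expect_setequal(ls_r$genes[[j]], manual)
    }
  }
  expect_error(assign_genes(ls, data.frame(gene_id = "bad", chrom = "chr1",
                                           start = 10, end = 10)), "malformed")
})

test_that("ranking modes order loci as stated", {
  hits <- data.frame(chrom = "chr1",
                     pos = c(1e6, 9e6),
                     log10p = c(-20, -10),
                     beta = c(0.1, 0.5),
                     maf = c(0.3, 0.01))
  ls <- group_hits_into_loci(hits)
  r_p <- rank_loci(ls, "min_p")
  expect_equal(r_p$loci$min_log10p, c(-20, -10))
  expect_equal(r_p$loci$rank, 1:2)
  r_b <- rank_loci(ls, "max_abs_beta_significant")
  expect_equal(r_b$loci$min_log10p, c(-10, -20)) # order reverses
  # loci without significant members are excluded with a note
  hits2 <- rbind(hits, data.frame(chrom = "chr1", pos = 20e6, log10p = -6,
                                  beta = 9, maf = 0.2))
  ls2 <- group_hits_into_loci(hits2)
  expect_message(r2 <- rank_loci(ls2, "max_abs_beta_significant"), "excluding")
  expect_equal(nrow(r2$loci), 2L)
})

test_that("power-matched selection follows the published walk", {
  hits <- data.frame(chrom = "chr1", pos = c(1, 5, 9) * 1e6,
                     log10p = c(-30, -20, -10))
  ls <- group_hits_into_loci(hits)
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(1, 5, 9) * 1e6 - 1e4,
                      end = c(1, 5, 9) * 1e6 + 1e4)
  ls <- rank_loci(assign_genes(ls, genes))
  burden <- data.frame(gene_id = c("a", "b", "c"),
                       log10p = c(-8, -8, -3))
  sel <- select_power_matched_top_loci(ls, burden)
  expect_equal(sel$target, 2L)
  expect_setequal(sel$genes, c("a", "b"))
  expect_length(sel$locus_ids, 2L)

  none <- select_power_matched_top_loci(
    ls, data.frame(gene_id = c("a", "b", "c"), log10p = c(-1, -1, -1)))
  expect_equal(none$target, 0L)
  expect_length(none$genes, 0L)
})

test_that("power-matched selection equals a literal procedural oracle", {
  set.seed(9)
  for (rep in 1:25) {
    hits <- random_hits(12, span = 3e7)
    n_g <- 40
    gstart <- sample.int(3.2e7, n_g)
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_g)),
                        chrom = paste0("chr", sample.int(2, n_g, TRUE)),
                        start = gstart, end = gstart + 5e4)
    burden <- data.frame(gene_id = genes$gene_id,
                         log10p = -runif(n_g, 0, 12))
    ls <- rank_loci(assign_genes(group_hits_into_loci(hits), genes))
    sel <- select_power_matched_top_loci(ls, burden, burden_threshold = 1e-6)

    # literal re-execution of the published paragraph
    sig <- burden$gene_id[burden$log10p < log10(1e-6)]
    target <- length(sig)
    chosen <- character(0)
    if (target > 0) {
      for (j in seq_len(nrow(ls$loci))) {
        gl <- ls$genes[[j]]
        if (length(gl) == 0) next
        in_sig <- intersect(gl, sig)
        if (length(in_sig) > 0) {
          chosen <- union(chosen, in_sig)
        } else {
          p <- burden$log10p[match(gl, burden$gene_id)]
          chosen <- union(chosen, gl[order(p, gl)][1])
        }
        if (length(chosen) >= target) break
      }
    }
    expect_setequal(sel$genes, chosen)
  }
})

test_that("burden-locus overlap fractions recover planted concordance", {
  # concordant world: every burden gene sits under the strongest hits
  hits <- data.frame(chrom = "chr1", pos = c(10, 30, 50) * 1e6,
                     log10p = c(-40, -30, -20))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(10, 30, 50) * 1e6, end = c(10, 30, 50) * 1e6 + 1e4)
  burden <- data.frame(gene_id = genes$gene_id, log10p = c(-10, -9, -8))
  ls <- rank_loci(assign_genes(group_hits_into_loci(hits), genes))
  top <- select_power_matched_top_loci(ls, burden)
  ov <- burden_gwas_overlap(burden, ls, top)
  expect_equal(ov$frac_in_any_locus, 1)
  expect_equal(ov$frac_in_top_loci, 1)
  expect_equal(ov$pairs$locus_rank, 1:3)

  far <- data.frame(gene_id = "lonely", chrom = "chr2", start = 1, end = 100)
  ls2 <- rank_loci(assign_genes(group_hits_into_loci(hits), far))
  ov2 <- burden_gwas_overlap(data.frame(gene_id = "lonely", log10p = -9), ls2)
  expect_equal(ov2$frac_in_any_locus, 0)

  # planted mixture: 60% of burden genes inside loci
  set.seed(10)
  n <- 200
  inside <- seq_len(n) <= 120
  gpos <- ifelse(inside, 10e6 + seq_len(n) * 1e3, 200e6 + seq_len(n) * 3e6)
  genes3 <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = "chr1",
                       start = gpos, end = gpos + 500)
  hits3 <- data.frame(chrom = "chr1", pos = 10.1e6, log10p = -30)
  burden3 <- data.frame(gene_id = genes3$gene_id, log10p = rep(-9, n))
  ls3 <- rank_loci(assign_genes(group_hits_into_loci(hits3), genes3))
  ov3 <- burden_gwas_overlap(burden3, ls3)
  expect_equal(ov3$frac_in_any_locus, 0.6)
})

test_that("LD block comparison drops blocks sharing a minimizing gene", {
  blocks <- data.frame(chrom = "chr1", start = c(0, 1e6, 2e6),
                       end = c(1e6, 2e6, 3e6))
  hits <- data.frame(chrom = "chr1", pos = c(5e5, 1.5e6, 2.5e6),
                     log10p = c(-12, -9, -22))
  genes <- data.frame(gene_id = c("span", "solo"), chrom = "chr1",
                      start = c(0.9e6, 2.2e6), end = c(1.1e6, 2.3e6))
  burden <- data.frame(gene_id = c("span", "solo"), log10p = c(-15, -4))
  cmp <- ld_block_compare(blocks, hits, burden, genes)
  expect_equal(cmp$min_gwas_log10p, c(-12, -9, -22))
  expect_equal(cmp$min_burden_gene, c("span", "span", "solo"))
  expect_equal(cmp$dropped, c(TRUE, TRUE, FALSE))
  expect_error(
    ld_block_compare(data.frame(chrom = "chr1", start = c(0, 5e5), end = c(1e6, 2e6)),
                     hits, burden, genes), "overlap")

  set.seed(11)
  for (rep in 1:15) {
    bl <- data.frame(chrom = "chr1", start = 0:9 * 1e6, end = 1:10 * 1e6)
    n_g <- 25
    gstart <- sample.int(9.8e6, n_g)
    gn <- data.frame(gene_id = sprintf("g%02d", seq_len(n_g)), chrom = "chr1",
                     start = gstart, end = gstart + sample.int(8e5, n_g))
    bd <- data.frame(gene_id = gn$gene_id, log10p = -runif(n_g, 0, 20))
    cmp_r <- ld_block_compare(bl, random_hits(15, n_chrom = 1, span = 1e7), bd, gn)
    dup <- cmp_r$min_burden_gene[duplicated(cmp_r$min_burden_gene) &
                                 !is.na(cmp_r$min_burden_gene)]
    expect_identical(cmp_r$dropped,
                     !is.na(cmp_r$min_burden_gene) & cmp_r$min_burden_gene %in% dup)
  }
})

test_that("MAF filtering is inclusive at the threshold", {
  hits <- data.frame(chrom = "chr1", pos = 1:4, log10p = rep(-9, 4),
                     maf = c(0.005, 0.01, 0.1, 0.5))
  expect_equal(nrow(filter_hits_by_maf(hits, 0.5)), 4L)
  expect_equal(nrow(filter_hits_by_maf(hits, 0.01)), 2L)
  expect_identical(filter_hits_by_maf(hits, 0.1)$pos, 1:3)
  expect_error(filter_hits_by_maf(hits, 0.7), "maf_threshold")
  set.seed(12)
  h <- random_hits(50)
  for (thr in c(0.05, 0.2, 0.5)) {
    expect_identical(filter_hits_by_maf(h, thr), h[h$maf <= thr, , drop = FALSE])
  }
})
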