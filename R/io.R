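# Readers/writers for the package's TSV and BED conventions, and the
# seeded pipeline orchestrator. P values are carried as log10 throughout;
# a linear `p` column in input files is converted with a notice.

summary_schemas <- list(
  gwas = c("variant_id", "chrom", "pos", "trait", "beta", "se", "maf"),
  burden = c("gene_id", "trait", "beta", "se", "p_lof")
)

#' Read a GWAS or burden summary-statistics TSV
#'
#' Validates required columns and invariants (positive SE, frequencies in
#' range, P values at most 1). A `p` column is converted to `log10p` with
#' a message; files may instead carry `log10p` directly.
#'
#' @param path file path.
#' @param schema `"gwas"` (per-variant) or `"burden"` (per-gene).
#' @return a validated data.frame with a `log10p` column.
#' @export
read_summary_tsv <- function(path, schema = c("gwas", "burden")) {
  schema <- match.arg(schema)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- summary_schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("log10p" %in% names(df))) {
    if (!("p" %in% names(df))) stop("need a 'p' or 'log10p' column")
    bad <- which(!is.finite(df$p) | df$p > 1 | df$p < 0)
    if (length(bad)) {
      stop(sprintf("invalid P value at row %d, column 'p'", bad[1L]))
    }
    message("converting linear 'p' column to log10p")
    df$log10p <- log10(df$p)
  }
  for (col in c("beta", "se", "log10p", intersect(c("maf", "p_lof", "pos"),
                                                  names(df)))) {
    bad <- which(!is.finite(df[[col]]) &
                 !(col == "log10p" & df[[col]] == -Inf))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite value at row %d, column '%s'",
                   bad[1L], col))
    }
  }
  if (any(df$se <= 0)) {
    stop(sprintf("non-positive SE at row %d, column 'se'", which(df$se <= 0)[1L]))
  }
  if (any(df$log10p > 0)) {
    stop(sprintf("P value above 1 at row %d, column 'log10p'",
                 which(df$log10p > 0)[1L]))
  }
  if ("maf" %in% names(df) && any(df$maf < 0 | df$maf > 0.5)) {
    stop("MAF outside [0, 0.5]")
  }
  if ("p_lof" %in% names(df) && any(df$p_lof < 0 | df$p_lof >= 1)) {
    stop("p_lof outside [0, 1)")
  }
  message(sprintf("read %d rows from %s", nrow(df), path))
  df
}

#' Write a summary table as TSV
#' @param df a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_summary_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Standard tab-separated BED (0-based half-open), sorted by chromosome
#' and start, preceded by a single header comment line.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) > 0L && any(intervals$start >= intervals$end)) {
    stop("start must be < end for BED intervals")
  }
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  out <- intervals[order(intervals$chrom, intervals$start), cols, drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(out) > 0L) {
    utils::write.table(format(out, scientific = FALSE, trim = TRUE), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a BED file of intervals
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name` (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

#' Export a locus set as BED plus a companion TSV
#'
#' @param locus_set a `"locus_set"` (ranked and/or with genes assigned).
#' @param prefix output path prefix; writes `<prefix>_loci.bed` and
#'   `<prefix>_loci.tsv`.
#' @return invisibly, the two paths.
#' @export
write_loci <- function(locus_set, prefix) {
  stopifnot(inherits(locus_set, "locus_set"))
  loci <- locus_set$loci
  bed <- data.frame(chrom = loci$chrom, start = loci$start, end = loci$end,
                    name = paste0("locus", loci$locus_id))
  bed_path <- paste0(prefix, "_loci.bed")
  tsv_path <- paste0(prefix, "_loci.tsv")
  write_bed(bed, bed_path)
  tsv <- loci
  tsv$genes <- if (is.null(locus_set$genes)) "" else
    vapply(locus_set$genes, paste, character(1), collapse = ",")
  write_summary_tsv(tsv, tsv_path)
  invisible(c(bed_path, tsv_path))
}

pipeline_stages <- c("afs", "realized-h2", "pleiotropy-sim", "flattening")

#' Run a reproducible pipeline of simulation stages
#'
#' Executes a chain of named stages with per-stage random substreams
#' derived deterministically from the master seed via [stage_seed()], so
#' an identical configuration and seed reproduce every output and adding a
#' stage does not perturb the streams of the others. A plain-text manifest
#' capturing the configuration, seed and package version is written next
#' to the outputs.
#'
#' @param config list with elements `stages` (character vector from
#'   `"afs"`, `"realized-h2"`, `"pleiotropy-sim"`, `"flattening"`),
#'   `seed` (master seed), `out_prefix` (output path prefix), and optional
#'   stage parameter lists named after each stage. The `afs` grid is built
#'   once and shared by the stages that need it.
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$stages), !is.null(config$seed),
            !is.null(config$out_prefix))
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(pipeline_stages, collapse = ", "))
  }
  prefix <- config$out_prefix
  manifest <- c(sprintf("specdrift %s", as.character(utils::packageVersion("specdrift"))),
                sprintf("seed: %d", as.integer(config$seed)),
                sprintf("stages: %s", paste(config$stages, collapse = " -> ")))
  results <- list()
  grid <- NULL
  get_grid <- function() {
    if (is.null(grid)) {
      gp <- config$afs %||% list()
      grid <<- do.call(build_selection_grid, gp)
    }
    grid
  }
  for (st in config$stages) {
    seed_st <- stage_seed(config$seed, st)
    pars <- config[[st]] %||% list()
    manifest <- c(manifest, sprintf("stage %s: seed=%d params={%s}", st, seed_st,
                                    paste(names(pars), unlist(pars),
                                          sep = "=", collapse = ", ")))
    results[[st]] <- switch(st,
      "afs" = {
        g <- get_grid()
        write_selection_grid(g, paste0(prefix, "_afs"))
        g
      },
      "realized-h2" = {
        tab <- do.call(realized_heritability_experiment,
                       c(list(grid = get_grid(), seed = seed_st), pars))
        write_summary_tsv(tab, paste0(prefix, "_realized_h2.tsv"))
        tab
      },
      "pleiotropy-sim" = {
        res <- do.call(run_pleiotropy_simulation,
                       c(list(grid = get_grid(), seed = seed_st), pars))
        write_summary_tsv(res$profile, paste0(prefix, "_pleiotropy_profile.tsv"))
        res
      },
      "flattening" = {
        pars$gamma_grid <- pars$gamma_grid %||% exp(seq(log(1e-3), log(0.01),
                                                        length.out = 20))
        res <- do.call(flattening_analysis,
                       c(list(grid = get_grid(), seed = seed_st), pars))
        write_summary_tsv(res$per_gene, paste0(prefix, "_flattening_gene.tsv"))
        res
      })
  }
  writeLines(manifest, paste0(prefix, "_manifest.txt"))
  invisible(results)
}
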