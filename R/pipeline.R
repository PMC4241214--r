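#' End-to-end sample processing pipeline
#'
#' Runs the integrated post-alignment workflow over a set of samples:
#' QFI gate (pre-analytical qualification) -> depth filter -> systematic
#' variant blacklist -> sample-adaptive threshold search -> variant calls
#' -> optional orthogonal confirmation -> report. Samples are excluded with
#' an explicit reason (`QFI_FAIL`, `THRESHOLD_FAIL`, `NO_DATA`) rather than
#' silently dropped.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{samples}{named list of [sample_table()]s, or a character
#'       vector of TSV paths (named by sample id or using the file's
#'       sample_id).}
#'     \item{panel_kb}{panel size in kb (required).}
#'     \item{annotations}{a [annotation_set()] or TSV path.}
#'     \item{qfi}{optional: a [compute_qfi()] result covering the samples,
#'       or a list with `standards` (mass_ng, cq) and `samples`
#'       (sample_id, cq) data.frames/paths.}
#'     \item{qfi_gate_pct}{QFI pass threshold (default 3, strict `>`).}
#'     \item{sv_catalog}{optional SV blacklist (catalog, key vector, or SV
#'       TSV path).}
#'     \item{grid}{threshold grid list (min, max, step).}
#'     \item{constraints}{optional overrides passed to [constraint_set()].}
#'     \item{depth_filter}{list(min_reads, min_frac_median); default
#'       (100, 0.1).}
#'     \item{out_dir}{optional output directory for the JSON report and
#'       per-sample call TSVs.}
#'     \item{seed}{recorded in the report (the pipeline itself is
#'       deterministic).}
#'   }
#' @return A list of class `tas_pipeline_report`: `per_sample` status
#'   data.frame, `calls` (named list of call tables for passing samples),
#'   `summary` counts, and `provenance` (package version, config hash,
#'   seed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$panel_kb))
  samples <- config$samples
  if (is.null(samples) || length(samples) == 0) {
    stop("config$samples is empty; nothing to run\n",
      "usage: run_pipeline(list(samples = <tables or paths>, ",
      "panel_kb = <kb>, annotations = <set>, ...))"
    )
  }
  if (is.character(samples)) {
    samples <- lapply(samples, read_sample_table)
  }
  nm <- names(samples)
  if (is.null(nm) || any(nm == "")) {
    nm <- vapply(samples, function(s) s$sample_id[1], "")
    names(samples) <- nm
  }
  ann <- config$annotations
  if (is.character(ann)) ann <- read_annotations(ann)
  sv <- config$sv_catalog
  if (is.character(sv) && length(sv) == 1 && file.exists(sv)) {
    svdf <- utils::read.delim(sv, stringsAsFactors = FALSE)
    sv <- hyp_key(svdf$chrom, svdf$pos, svdf$ref, svdf$alt)
  }
  gate <- if (is.null(config$qfi_gate_pct)) 3 else config$qfi_gate_pct
  qfi <- config$qfi
  if (is.list(qfi) && !inherits(qfi, "tas_qfi_result")) {
    std <- qfi$standards
    if (is.character(std)) std <- utils::read.delim(std)
    smp <- qfi$samples
    if (is.character(smp)) smp <- utils::read.delim(smp)
    curve <- fit_calibration(std$mass_ng, std$cq)
    qfi <- compute_qfi(smp$sample_id, smp$cq, curve, gate_pct = gate)
  }
  cs_args <- c(list(panel_kb = config$panel_kb), config$constraints)
  cs <- do.call(constraint_set, cs_args)
  df_par <- config$depth_filter
  if (is.null(df_par)) df_par <- list(min_reads = 100, min_frac_median = 0.1)
  grid <- config$grid
  if (is.null(grid)) grid <- list(min = 2, max = 20, step = 0.5)

  status <- reason <- character(length(samples))
  tgc <- tot <- pann <- cpk <- titv <- rep(NA_real_, length(samples))
  qfi_pct <- rep(NA_real_, length(samples))
  calls <- list()
  for (i in seq_along(samples)) {
    id <- names(samples)[i]
    s <- samples[[i]]
    if (nrow(s) == 0) {
      status[i] <- "EXCLUDED"
      reason[i] <- "NO_DATA"
      next
    }
    if (!is.null(qfi)) {
      row <- match(id, qfi$sample_id)
      if (is.na(row)) {
        status[i] <- "EXCLUDED"
        reason[i] <- "NO_DATA"
        next
      }
      qfi_pct[i] <- qfi$qfi_percent[row]
      if (qfi$tier[row] != "PASS") {
        status[i] <- "EXCLUDED"
        reason[i] <- "QFI_FAIL"
        next
      }
    }
    sf <- depth_filter(s, df_par$min_reads, df_par$min_frac_median)
    pair <- grid_search(sf, ann, cs, grid)
    if (pair$status != "PASS") {
      status[i] <- "EXCLUDED"
      reason[i] <- "THRESHOLD_FAIL"
      next
    }
    status[i] <- "PASS"
    reason[i] <- ""
    tgc[i] <- pair$t_gc_at
    tot[i] <- pair$t_other
    pann[i] <- pair$metrics$pct_annotated
    cpk[i] <- pair$metrics$calls_per_kb
    titv[i] <- pair$metrics$titv
    calls[[id]] <- call_variants(sf, pair, sv)
  }
  per_sample <- data.frame(
    sample_id = names(samples), status = status, reason = reason,
    qfi_percent = qfi_pct, t_gc_at = tgc, t_other = tot,
    pct_annotated = pann, calls_per_kb = cpk, titv = titv,
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      per_sample = per_sample, calls = calls,
      summary = list(
        n_samples = length(samples), n_pass = sum(status == "PASS"),
        n_qfi_fail = sum(reason == "QFI_FAIL"),
        n_threshold_fail = sum(reason == "THRESHOLD_FAIL"),
        n_no_data = sum(reason == "NO_DATA")
      ),
      provenance = list(
        package = "tasqc",
        version = as.character(utils::packageVersion("tasqc")),
        config_hash = rlang::hash(config),
        seed = config$seed, timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "tas_pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_report(report, config$out_dir)
  }
  report
}

#' @rdname run_pipeline
#' @param report A `tas_pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      summary = report$summary, provenance = report$provenance,
      per_sample = report$per_sample
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.table(report$per_sample,
    file.path(out_dir, "per_sample.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (id in names(report$calls)) {
    write_sample_table(
      report$calls[[id]],
      file.path(out_dir, paste0("calls_", id, ".tsv"))
    )
  }
  invisible(out_dir)
}

#' @export
print.tas_pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<tas_pipeline_report> %d samples: %d PASS, %d QFI_FAIL, %d THRESHOLD_FAIL, %d NO_DATA\n",
    s$n_samples, s$n_pass, s$n_qfi_fail, s$n_threshold_fail, s$n_no_data
  ))
  invisible(x)
}
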