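#' Run the full reference-gene workflow from a configuration
#'
#' Orchestrates the stages simulate, screen, stability, aggregate and
#' regress in order, writing every result as TSV plus a JSON manifest
#' (config echo, input hashes, package version, seed) so a run can be
#' reproduced exactly. Stages may be restricted; later stages read the
#' on-disk outputs of earlier ones when their inputs are not given as
#' files, so `run_pipeline` twice with the same seed yields byte-identical
#' tables. A failing stage raises an error naming the stage and leaves any
#' half-written table with a `.partial` suffix.
#'
#' @param config Named list or path to a YAML file with (all optional
#'   except `out_dir`): `out_dir`; `seed` (default 1); `stages` (subset of
#'   simulate/screen/stability/aggregate/regress, default all);
#'   `tpm_file`+`sample_sheet` and/or `ct_file` to analyse real data
#'   instead of simulating; `screen` (list: min_mean, max_sd, max_cv,
#'   top_n); `stability` (list: efficiency, use_groups); `simulate` (list
#'   of [synthetic_spec()] overrides, e.g. `panel_size`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("simulate", "screen", "stability", "aggregate", "regress")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  say <- function(...) if (!quiet) inform(sprintf(...))
  out <- function(f) file.path(config$out_dir, f)
  emit <- function(tbl, f) {
    partial <- paste0(out(f), ".partial")
    write_result_table(tbl, partial)
    file.rename(partial, out(f))
  }
  results <- list()

  spec <- do.call(synthetic_spec,
                  c(config$simulate[setdiff(names(config$simulate), "panel_size")] %||% list(),
                    list(seed = seed)))
  expr <- NULL
  ct <- NULL
  run_stage <- function(name, body) {
    say("[refstab] stage %s", name)
    tryCatch(body(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      expr <<- simulate_expression(spec)
      panel_size <- config$simulate$panel_size %||% 10L
      truth <- attr(expr, "truth")
      panel <- c(head(truth$gene_id[truth$status == "stable"], ceiling(panel_size / 2)),
                 head(truth$gene_id[truth$status == "unstable"], floor(panel_size / 2)))
      ct <<- simulate_ct(expr, spec, panel = panel)
      emit(expr, "expression.tsv")
      emit(attr(expr, "sample_sheet"), "sample_sheet.tsv")
      emit(ct, "ct.tsv")
      emit(truth, "truth.tsv")
      results$simulate <<- list(expr = expr, ct = ct, truth = truth)
    })
  }
  load_expr <- function() {
    if (!is.null(expr)) return(expr)
    path <- config$tpm_file %||% out("expression.tsv")
    sheet <- config$sample_sheet %||% out("sample_sheet.tsv")
    if (!file.exists(path)) abort(sprintf("expression input not found: %s", path))
    expr <<- read_expression(path, sheet)
    expr
  }
  load_ct <- function() {
    if (!is.null(ct)) return(ct)
    path <- config$ct_file %||% out("ct.tsv")
    if (!file.exists(path)) abort(sprintf("Ct input not found: %s", path))
    ct <<- read_ct(path)
    ct
  }

  if ("screen" %in% stages) {
    run_stage("screen", function() {
      sc <- config$screen %||% list()
      screen <- load_expr() |>
        collapse_replicates() |>
        gene_log_stats() |>
        screen_candidates(min_mean = sc$min_mean %||% 5,
                          max_sd = sc$max_sd %||% 1,
                          max_cv = sc$max_cv %||% 0.2)
      emit(screen$stats, "screen_stats.tsv")
      if (screen$n_candidates > 0) {
        emit(screen$candidates, "candidates.tsv")
        emit(top_candidates(screen, sc$top_n %||% 10), "top_candidates.tsv")
      }
      writeLines(screen_summary_line(screen), out("screen_summary.txt"))
      say("[refstab] %s candidate reference genes", screen_summary_line(screen))
      results$screen <<- screen
    })
  }

  if ("stability" %in% stages) {
    run_stage("stability", function() {
      st <- config$stability %||% list()
      ct_tbl <- load_ct()
      q <- ct_to_quantity(ct_tbl, efficiency = st$efficiency %||% 2)
      gn <- genorm(q)
      groups <- if (isTRUE(st$use_groups)) NULL else FALSE
      nf <- if (isFALSE(groups)) normfinder(ct_tbl, groups = NULL) else normfinder(ct_tbl)
      bk <- bestkeeper(ct_tbl)
      dc <- delta_ct(ct_tbl)
      emit(gn$ranking, "genorm.tsv")
      emit(gn$pairwise_variation, "genorm_v.tsv")
      emit(nf$ranking, "normfinder.tsv")
      emit(bk$ranking, "bestkeeper.tsv")
      emit(dc$ranking, "deltact.tsv")
      results$stability <<- list(genorm = gn, normfinder = nf,
                                 bestkeeper = bk, deltact = dc)
    })
  }

  if ("aggregate" %in% stages) {
    run_stage("aggregate", function() {
      stab <- results$stability
      if (is.null(stab)) abort("aggregate requires the stability stage")
      agg <- comprehensive_ranking(stab$genorm, stab$normfinder,
                                   stab$bestkeeper, stab$deltact)
      emit(agg, "comprehensive_ranking.tsv")
      results$aggregate <<- agg
    })
  }

  if ("regress" %in% stages) {
    run_stage("regress", function() {
      expr_m <- wide_to_matrix(load_expr())
      ct_m <- wide_to_matrix(load_ct())
      genes <- intersect(rownames(expr_m), rownames(ct_m))
      samples <- intersect(colnames(expr_m), colnames(ct_m))
      pairs <- tibble::tibble(
        log2tpm = as.vector(log2(expr_m[genes, samples])),
        ct = as.vector(ct_m[genes, samples]))
      fit <- fit_tpm_ct(pairs)
      emit(tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                          r_squared = fit$r_squared, p_value = fit$p_value,
                          n = fit$n), "calibration.tsv")
      say("[refstab] Ct = %.4f log2(TPM) + %.2f (R^2 = %.4f)",
          fit$slope, fit$intercept, fit$r_squared)
      results$regress <<- fit
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("refstab")),
    seed = seed,
    stages = as.list(stages),
    config = config[setdiff(names(config), "out_dir")],
    outputs = local({
      fs <- setdiff(list.files(config$out_dir), "manifest.json")
      lapply(setNames(fs, fs), function(f) {
        unname(tools::md5sum(file.path(config$out_dir, f)))
      })
    }),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
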