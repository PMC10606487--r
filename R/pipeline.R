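#' Run the full EDSP linkage pipeline from a configuration
#'
#' Orchestrates simulate -> select -> IBD -> linkage -> summary (and
#' optionally the power calculator) from a single configuration, writing
#' schema-stable TSV/CSV outputs and a log with the seeds and staged counts.
#' Given the same configuration the outputs are byte-identical across runs.
#'
#' The configuration is a nested list (or the path of a YAML file with the
#' same structure; see the packaged `demo.yaml`):
#' \describe{
#'   \item{simulate}{`n_families`, `seed`, optional `model` (arguments of
#'     [trait_model()]) and `markers`: either `panel: table1` with `theta`
#'     (and optional `chromosome`, `n_alleles`), or a list of marker entries
#'     (`name`, `n_alleles`, `theta`). `mask_parents` (default `TRUE`).}
#'   \item{select}{arguments of [selection_criteria()] plus optional
#'     `method` (`threshold`/`centile`).}
#'   \item{linkage}{`phenotypes` (default sbp, dbp, pp), `adjust`, and
#'     optional `lrt: {n_perm, seed, direction}` to add the allele-sharing
#'     LRT per marker.}
#'   \item{power}{optional; `run: true` plus `n_sim`, `seed`, `alpha`,
#'     `power` to compare EDSP against the unselected design.}
#' }
#'
#' @param config A nested list or path to a YAML file.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, an object of class `edsp_run`: list with `paths` of
#'   the written files and the in-memory `cohort`, `selected`, `sharing`,
#'   `results`, `summary` (and `power`) objects.
#' @examples
#' \donttest{
#' cfg <- system.file("extdata", "demo.yaml", package = "edsplink")
#' run <- edsp_pipeline(cfg, output_dir = tempfile("edsp"))
#' run$results
#' }
#' @export
edsp_pipeline <- function(config, output_dir = tempfile("edsp_run")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$simulate)) {
    stop("pipeline error [config]: need a list with at least a `simulate` section")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline error [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## --- simulate -----------------------------------------------------------
  sim_cfg <- config$simulate
  cohort <- stage("simulate", {
    if (is.null(sim_cfg$seed)) stop("`simulate$seed` is required")
    model <- do.call(trait_model, as.list(sim_cfg$model))
    markers <- .config_markers(sim_cfg$markers)
    ch <- simulate_families(sim_cfg$n_families %||% 200L, model, markers,
                            seed = sim_cfg$seed)
    if (isTRUE(sim_cfg$mask_parents %||% TRUE)) ch <- mask_parents(ch)
    ch
  })
  note("simulate: %d families, %d markers, seed %d",
       nrow(cohort$pairs), length(cohort$markers), cohort$seed)
  paths <- list(ped = file.path(output_dir, "cohort.ped"),
                map = file.path(output_dir, "markers.tsv"),
                pheno = file.path(output_dir, "phenotypes.csv"))
  write_ped(cohort, paths$ped)
  write_marker_map(cohort$markers, paths$map)
  off <- cohort$individuals[cohort$individuals$role == "offspring", ]
  write_phenotypes(data.frame(family_id = off$family_id,
                              individual_id = off$individual_id,
                              sex = off$sex, age = off$age,
                              sbp = off$sbp, dbp = off$dbp),
                   paths$pheno)

  ## --- select -------------------------------------------------------------
  sel_cfg <- as.list(config$select)
  method <- sel_cfg$method %||% "threshold"
  sel_cfg$method <- NULL
  selected <- stage("select", {
    crit <- do.call(selection_criteria, sel_cfg)
    select_edsp(cohort, crit, method = method)
  })
  cnt <- attr(selected, "counts")
  note("select: %d families -> %d past screen -> %d extreme discordant pairs",
       cnt[["n_families"]], cnt[["n_screened"]], cnt[["n_edsp"]])
  paths$pairs <- file.path(output_dir, "pairs.tsv")
  write_results(selected, paths$pairs)
  if (nrow(selected) == 0L) stop("pipeline error [select]: no extreme discordant pairs")

  ## --- ibd ----------------------------------------------------------------
  sharing <- stage("ibd", sharing_table(cohort, pairs = selected))
  note("ibd: %d pair-marker posteriors (%d informative)",
       nrow(sharing), sum(sharing$informative))
  paths$sharing <- file.path(output_dir, "sharing.tsv")
  write_results(sharing, paths$sharing)

  ## --- linkage ------------------------------------------------------------
  lk_cfg <- as.list(config$linkage)
  results <- lrt <- NULL
  if (isTRUE(lk_cfg$run %||% TRUE)) {
  results <- stage("linkage", {
    pp <- pair_phenotypes(cohort, selected)
    edsp_scan(sharing, pp,
              phenotypes = lk_cfg$phenotypes %||% c("sbp", "dbp", "pp"),
              adjust = lk_cfg$adjust %||% TRUE)
  })
  if (!is.null(lk_cfg$lrt)) {
    lrt <- stage("linkage", {
      lapply(stats::setNames(nm = unique(sharing$marker)), function(mk) {
        sh <- sharing[sharing$marker == mk & sharing$informative, ]
        sharing_lrt(sh[c("f0", "f1", "f2")],
                    direction = lk_cfg$lrt$direction %||% "any",
                    n_perm = lk_cfg$lrt$n_perm %||% 1000L,
                    seed = lk_cfg$lrt$seed %||% 1L)
      })
    })
  }
  note("linkage: %d marker x phenotype tests", nrow(results))
  paths$results <- file.path(output_dir, "results.tsv")
  write_results(results, paths$results)
  } else {
    note("linkage: skipped (sharing.tsv is the terminal output)")
  }

  ## --- summary ------------------------------------------------------------
  summ <- NULL
  if (isTRUE(config$summary$run %||% TRUE)) {
    summ <- stage("summary", cohort_summary(cohort, selected))
    paths$summary <- file.path(output_dir, "summary.tsv")
    write_results(summ, paths$summary)
    note("summary: %d variables", nrow(summ))
  }

  ## --- power (optional) ---------------------------------------------------
  pw <- NULL
  if (isTRUE(config$power$run)) {
    pw_cfg <- config$power
    pw <- stage("power", {
      model <- do.call(trait_model, as.list(sim_cfg$model))
      fold_reduction(model,
                     design_spec("edsp"), design_spec("unselected"),
                     alpha = pw_cfg$alpha %||% 0.05,
                     power = pw_cfg$power %||% 0.8,
                     n_sim = pw_cfg$n_sim %||% 50000,
                     seed = pw_cfg$seed %||% sim_cfg$seed)
    })
    note("power: fold reduction %.1f (EDSP n = %s vs comparison n = %s)",
         pw$fold_vs_comparison, format(pw$n_required_edsp),
         format(pw$n_required_comparison))
  }

  paths$log <- file.path(output_dir, "run.log")
  writeLines(log_lines, paths$log)
  invisible(structure(list(paths = paths, cohort = cohort,
                           selected = selected, sharing = sharing,
                           results = results, summary = summ,
                           lrt = lrt, power = pw),
                      class = "edsp_run"))
}

#' @export
print.edsp_run <- function(x, ...) {
  cat("EDSP pipeline run\n")
  cat("  outputs:", paste(basename(unlist(x$paths)), collapse = ", "), "\n")
  cat(sprintf("  %d selected pairs, %d linkage tests\n",
              nrow(x$selected),
              if (is.null(x$results)) 0L else nrow(x$results)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_markers <- function(mk_cfg) {
  if (is.null(mk_cfg)) stop("`simulate$markers` is required")
  if (!is.null(mk_cfg$panel)) {
    if (!identical(mk_cfg$panel, "table1")) {
      stop("unknown marker panel: ", mk_cfg$panel)
    }
    return(marker_panel(theta = mk_cfg$theta %||% 0.05,
                        n_alleles = mk_cfg$n_alleles %||% 8,
                        chromosome = mk_cfg$chromosome))
  }
  lapply(mk_cfg, function(m) {
    marker_def(m$name, n_alleles = m$n_alleles %||% 8,
               theta = m$theta %||% stop("marker without `theta`"),
               chromosome = as.character(m$chromosome %||% NA_character_))
  })
}
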