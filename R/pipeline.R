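#' Configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters.  Stage toggles allow skipping the
#' nonparametric screen (`npirt`), the network (`network`) or the benefit
#' stage; disabled stages are recorded in the run manifest and downstream
#' stages consume the most recent available matrix.
#'
#' @param seed master seed; each stage derives its own child seed, all
#'   recorded in the manifest.
#' @param stages character vector of enabled stages, a subset of
#'   `c("preprocess", "npirt", "pirt", "montecarlo", "network", "benefit")`.
#' @param missing_threshold,pseudo_constant_threshold item filter bounds.
#' @param lca_k_range candidate class counts for MILCA / LCRC.
#' @param aisp_lower_bound Mokken selection bound (default 0.42).
#' @param models candidate IRT models for selection.
#' @param mc_reps Monte-Carlo difficulty replicates (default 500).
#' @param bsl_iterations structure-search iterations (default 50000).
#' @param benefit_reps,benefit_batches benefit-stage Monte Carlo sizes.
#' @param quadrature quadrature points for EM and EAP.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("preprocess", "npirt", "pirt",
                                       "montecarlo", "network", "benefit"),
                            missing_threshold = 0.30,
                            pseudo_constant_threshold = 0.05,
                            lca_k_range = 1:6,
                            aisp_lower_bound = 0.42,
                            models = c("1PL", "2PL", "3PL", "4PL"),
                            mc_reps = 500,
                            bsl_iterations = 50000,
                            benefit_reps = 2000,
                            benefit_batches = 50,
                            quadrature = 61) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write/read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param file path to a YAML file.
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(file) {
  do.call(pipeline_config, yaml::read_yaml(file))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order on a (possibly incomplete)
#' function-coded response matrix: item filtering and MILCA imputation;
#' Mokken screening with Guttman-error person removal; 1PL-4PL fitting
#' with model selection, reliability and EAP scoring; Monte-Carlo-adjusted
#' difficulties; risk recoding, Bayesian structure learning and Ising
#' estimation; and the perturbation benefit analysis.  Every stage's seed
#' and outcome is recorded in the run `manifest`, which suffices to
#' reproduce the run.
#'
#' @param m a function-coded [response_matrix()] (raw qualifiers can be
#'   converted first with [dichotomize_icf()]).
#' @param config a [pipeline_config()].
#' @param resume optional earlier `icfnet_pipeline` result whose completed
#'   stage outputs are reused where the configuration allows.
#' @return An object of class `icfnet_pipeline` with one element per stage
#'   plus `manifest`.
#' @export
run_pipeline <- function(m, config = pipeline_config(), resume = NULL) {
  t0 <- Sys.time()
  seeds <- setNames(child_seeds(config$seed, 6),
                    c("preprocess", "npirt", "pirt", "montecarlo",
                      "network", "benefit"))
  out <- list(config = config)
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   stages = list(), started = format(t0))
  enabled <- function(s) s %in% config$stages
  reuse <- function(s) if (!is.null(resume) && !is.null(resume[[s]]))
    resume[[s]] else NULL
  run_stage <- function(name, fun) {
    cached <- reuse(name)
    if (!is.null(cached)) {
      manifest$stages[[name]] <<- list(status = "resumed")
      return(cached)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      res
    }
  }
  m <- as_response_matrix(m)

  current <- m
  if (enabled("preprocess")) {
    out$preprocess <- run_stage("preprocess", function() {
      filt <- filter_items(m, config$missing_threshold,
                           config$pseudo_constant_threshold)
      mat <- filt$matrix
      lca <- NULL
      if (anyNA(mat)) {
        lca <- select_lca_k(mat, config$lca_k_range,
                            seed = seeds[["preprocess"]])
        mat <- milca_impute(mat, lca, seed = seeds[["preprocess"]])
      }
      list(filter = filt, lca = lca, matrix = mat)
    })
    if (is.null(out$preprocess)) return(finish(out, manifest))
    current <- out$preprocess$matrix
  }
  if (enabled("npirt")) {
    out$npirt <- run_stage("npirt", function() {
      sel <- aisp_select(current, config$aisp_lower_bound)
      kept <- if (length(sel$selected)) sel$selected else colnames(current)
      mat <- response_matrix(unclass_rm(current)[, kept, drop = FALSE],
                             orientation(current),
                             person_ids = rownames(current), item_ids = kept)
      ge <- guttman_errors(mat)
      flagged <- flag_aberrant_persons(ge)
      keep_persons <- setdiff(rownames(mat), flagged)
      mat <- response_matrix(
        unclass_rm(mat)[keep_persons, , drop = FALSE], orientation(mat),
        person_ids = keep_persons, item_ids = kept)
      list(selection = sel, guttman = ge, flagged_persons = flagged,
           mokken = scalability_coefficients(mat),
           monotonicity = check_monotonicity(mat), matrix = mat)
    })
    if (!is.null(out$npirt)) current <- out$npirt$matrix
    else manifest$stages$npirt$note <- "npirt failed; pirt uses previous matrix"
  } else {
    manifest$stages$npirt <- list(status = "disabled",
                                  note = "pirt consumes the preprocessed matrix")
  }
  if (enabled("pirt")) {
    out$pirt <- run_stage("pirt", function() {
      fits <- lapply(config$models, function(mod)
        suppressWarnings(fit_irt(current, mod, n_quad = config$quadrature)))
      names(fits) <- config$models
      cmp <- compare_models(fits, current)
      best <- fits[[cmp$selected]]
      rel <- reliability(current, seed = seeds[["pirt"]])
      abil <- predict(best)
      list(fits = fits, comparison = cmp, fit = best, reliability = rel,
           abilities = abil)
    })
    if (is.null(out$pirt)) return(finish(out, manifest))
  }
  if (enabled("montecarlo") && !is.null(out$pirt)) {
    out$montecarlo <- run_stage("montecarlo", function()
      monte_carlo_difficulty(out$pirt$fit, reps = config$mc_reps,
                             seed = seeds[["montecarlo"]]))
    if (!is.null(out$montecarlo)) out$pirt$fit$item_bank <- out$montecarlo
  }
  if (enabled("network")) {
    out$network <- run_stage("network", function() {
      risk <- recode_for_network(current)
      bsl <- bsl_structure_search(risk, iterations = config$bsl_iterations,
                                  seed = seeds[["network"]])
      graph <- select_graph(bsl)
      model <- estimate_ising(risk, graph)
      model$edge_posterior <- bsl$edge_posterior
      list(risk = risk, bsl = bsl, graph = graph, model = model,
           main_component = maximal_connected_component(graph))
    })
  }
  if (enabled("benefit") && !is.null(out$network)) {
    out$benefit <- run_stage("benefit", function() {
      cfg <- perturbation_config(reps = config$benefit_reps,
                                 batches = config$benefit_batches,
                                 seed = seeds[["benefit"]])
      method <- if (length(out$network$model$tau) <= 20) "exact" else "gibbs"
      benefit_analysis(out$network$model, cfg, method = method)
    })
  }
  finish(out, manifest)
}

finish <- function(out, manifest) {
  manifest$finished <- format(Sys.time())
  out$manifest <- manifest
  class(out) <- "icfnet_pipeline"
  out
}

#' @export
print.icfnet_pipeline <- function(x, ...) {
  st <- vapply(x$manifest$stages, `[[`, "", "status")
  cat("<icfnet_pipeline>\n")
  for (nm in names(st)) cat(sprintf("  %-11s %s\n", nm, st[nm]))
  invisible(x)
}

#' Human-readable pipeline report
#'
#' One document summarizing the selected model, reliability, the item
#' table, the network and the benefit ranking; stages that did not run are
#' marked "not run".
#'
#' @param x an `icfnet_pipeline` result.
#' @param file optional path; when `NULL` the lines are returned.
#' @return Character vector of report lines, invisibly when written.
#' @export
export_report <- function(x, file = NULL) {
  ln <- c("ICF nutrition-health analysis report",
          strrep("=", 38))
  if (!is.null(x$pirt)) {
    rel <- x$pirt$reliability
    ln <- c(ln, sprintf("Selected model: %s", x$pirt$comparison$selected),
            sprintf("Reliability: Cronbach alpha %.3f, LCRC %.3f (K = %d)",
                    rel$cronbach_alpha, rel$lcrc, rel$K),
            "", "Item parameters:",
            utils::capture.output(print.data.frame(
              as.data.frame(x$pirt$fit$item_bank), digits = 3)))
  } else ln <- c(ln, "IRT stage: not run")
  if (!is.null(x$network)) {
    ln <- c(ln, "",
            sprintf("Network: %d items, %d edges; main component %d items",
                    length(x$network$model$tau),
                    sum(x$network$graph[upper.tri(x$network$graph)]),
                    length(x$network$main_component)))
  } else ln <- c(ln, "Network stage: not run")
  if (!is.null(x$benefit)) {
    ord <- order(-x$benefit$bi_raw)
    ln <- c(ln, "", "Benefit ranking:",
            utils::capture.output(print.data.frame(
              as.data.frame(x$benefit)[ord, ], digits = 3)))
  } else ln <- c(ln, "Benefit stage: not run")
  if (is.null(file)) return(ln)
  writeLines(ln, file)
  invisible(ln)
}
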