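#' Fit the nested model ladder
#'
#' Builds the genomic relationship matrices once, then fits each requested
#' model (default: A, A+D, A+D+AA, A+D+AA+AD, A+D+AA+AD+DD) by Gibbs
#' sampling on the same data, returning per-model posterior summaries, the
#' DIC table, and the additive/dominance orthogonality deltas across the
#' ladder.
#'
#' @param genotypes a [genotype_matrix()].
#' @param records phenotype `data.frame` (see [build_design()]).
#' @param models list of character vectors of genetic terms.
#' @param cfg a [chain_config()].
#' @param inbreeding_covariate include f in every model?
#' @param priors a [vc_priors()].
#' @param grms optional precomputed list from [build_grms()] (shared
#'   across models; computed if `NULL`).
#' @return List of class `nested_models_report`: `summaries` (per model),
#'   `chains`, `dic_table`, `orthogonality`, `grms`.
#' @export
run_nested_models <- function(genotypes, records,
                              models = list("A", c("A", "D"),
                                            c("A", "D", "AA"),
                                            c("A", "D", "AA", "AD"),
                                            c("A", "D", "AA", "AD", "DD")),
                              cfg = chain_config(20000, 2000, 10),
                              inbreeding_covariate = TRUE,
                              priors = vc_priors(),
                              grms = NULL) {
  needed <- unique(unlist(models))
  if (is.null(grms)) grms <- build_grms(genotypes, components = needed)
  f <- genomic_inbreeding(genotypes)
  labels <- vapply(models, paste, character(1), collapse = "+")
  chains <- summaries <- vector("list", length(models))
  names(chains) <- names(summaries) <- labels
  for (i in seq_along(models)) {
    spec <- model_spec(models[[i]],
                       inbreeding_covariate = inbreeding_covariate)
    design <- build_design(records, spec, f,
                           individuals = genotypes$individual_ids)
    chains[[i]] <- gibbs_sample(design, grms, priors = priors, cfg = cfg)
    summaries[[i]] <- variance_ratios(chains[[i]])
  }
  dic_table <- data.frame(
    model = labels,
    DIC = vapply(summaries, function(s) s$dic, numeric(1)),
    pD = vapply(summaries, function(s) s$pD, numeric(1)),
    row.names = NULL)
  comp_mean <- function(s, comp) {
    i <- match(comp, s$components$component)
    if (is.na(i)) NA_real_ else s$components$mean[i]
  }
  comp_sd <- function(s, comp) {
    i <- match(comp, s$components$component)
    if (is.na(i)) NA_real_ else s$components$sd[i]
  }
  orth <- data.frame(
    model = labels,
    var_A = vapply(summaries, comp_mean, numeric(1), comp = "A"),
    sd_A = vapply(summaries, comp_sd, numeric(1), comp = "A"),
    var_D = vapply(summaries, comp_mean, numeric(1), comp = "D"),
    sd_D = vapply(summaries, comp_sd, numeric(1), comp = "D"),
    row.names = NULL)
  structure(list(summaries = summaries, chains = chains,
                 dic_table = dic_table, orthogonality = orth,
                 grms = grms, config = cfg),
            class = "nested_models_report")
}

#' @export
print.nested_models_report <- function(x, ...) {
  cat("Nested genomic models:\n")
  print(cbind(x$orthogonality, DIC = round(x$dic_table$DIC, 1)))
  invisible(x)
}

#' Inbreeding-covariate contrast (GDIF vs GDI)
#'
#' Fits the same model twice on identical data and identical relationship
#' matrices: once including the genomic-inbreeding covariate (GDIF) and
#' once omitting it (GDI). Under directional dominance, omitting the
#' covariate inflates the dominance variance estimate.
#'
#' @inheritParams run_nested_models
#' @param terms genetic terms of the model fitted in both variants.
#' @return List of class `inbreeding_contrast`: `with_f` and `without_f`
#'   variance summaries, the shared `grms`, and the dominance-variance
#'   delta.
#' @export
run_inbreeding_contrast <- function(genotypes, records,
                                    terms = c("A", "D", "AA", "AD", "DD"),
                                    cfg = chain_config(20000, 2000, 10),
                                    priors = vc_priors(),
                                    grms = NULL) {
  if (is.null(grms)) grms <- build_grms(genotypes, components = terms)
  f <- genomic_inbreeding(genotypes)
  fits <- lapply(c(TRUE, FALSE), function(use_f) {
    spec <- model_spec(terms, inbreeding_covariate = use_f)
    design <- build_design(records, spec, f,
                           individuals = genotypes$individual_ids)
    variance_ratios(gibbs_sample(design, grms, priors = priors, cfg = cfg))
  })
  mean_D <- function(s) s$components$mean[s$components$component == "D"]
  structure(list(with_f = fits[[1]], without_f = fits[[2]],
                 grms = grms,
                 delta_var_D = mean_D(fits[[2]]) - mean_D(fits[[1]])),
            class = "inbreeding_contrast")
}

#' @export
print.inbreeding_contrast <- function(x, ...) {
  dW <- x$with_f$components
  dO <- x$without_f$components
  cat("GDIF (with f) vs GDI (without f):\n")
  cat(sprintf("  var_D: %.4f -> %.4f (delta %.4f)\n",
              dW$mean[dW$component == "D"], dO$mean[dO$component == "D"],
              x$delta_var_D))
  if (!is.null(x$with_f$b)) {
    cat(sprintf("  b (GDIF) = %.2f +/- %.2f\n",
                x$with_f$b["mean"], x$with_f$b["sd"]))
  }
  invisible(x)
}

#' Forward validation across models
#'
#' Splits the records at a time cutoff, fits each model by GBLUP at fixed
#' variance components on the whole and partial data, and reports the
#' method-R triple (b0, b1, rho) on candidate EBV plus the predictive
#' ability (correlation and slope of y* on yhat) on candidate records.
#'
#' @inheritParams run_nested_models
#' @param cutoff period cutoff passed to [time_split()].
#' @param variances named variances used by [solve_gblup()] — either one
#'   vector reused for every model or a list keyed like `models`. When
#'   `NULL`, each model's variances are first estimated by Gibbs sampling
#'   on the whole data.
#' @param models list of term vectors (default A, A+D, full).
#' @return List of class `validation_report_set`: per-model `method_r` and
#'   `predictive_ability`, the `split_plan`, and the variances used.
#' @export
run_validation <- function(genotypes, records, cutoff,
                           models = list("A", c("A", "D"),
                                         c("A", "D", "AA", "AD", "DD")),
                           variances = NULL,
                           cfg = chain_config(20000, 2000, 10),
                           inbreeding_covariate = TRUE,
                           grms = NULL) {
  needed <- unique(unlist(models))
  if (is.null(grms)) grms <- build_grms(genotypes, components = needed)
  f <- genomic_inbreeding(genotypes)
  split <- time_split(records, cutoff)
  labels <- vapply(models, paste, character(1), collapse = "+")
  out <- vector("list", length(models))
  names(out) <- labels
  used_vars <- vector("list", length(models))
  names(used_vars) <- labels
  for (i in seq_along(models)) {
    spec <- model_spec(models[[i]],
                       inbreeding_covariate = inbreeding_covariate)
    dw <- build_design(split$whole, spec, f,
                       individuals = genotypes$individual_ids)
    dp <- build_design(split$partial, spec, f,
                       individuals = genotypes$individual_ids)
    v <- if (is.null(variances)) {
      s <- variance_ratios(gibbs_sample(dw, grms, cfg = cfg))
      stats::setNames(s$components$mean, s$components$component)
    } else if (is.list(variances) && !is.null(variances[[labels[i]]])) {
      variances[[labels[i]]]
    } else {
      unlist(variances)
    }
    used_vars[[i]] <- v
    solw <- solve_gblup(dw, grms, v)
    solp <- solve_gblup(dp, grms, v)
    mr <- method_r(solw$g[, "A"], solp$g[, "A"], split$candidates,
                   sigma_a = sqrt(v[["A"]]))
    cand_rec <- split$whole[as.character(split$whole$id) %in%
                              split$candidates, , drop = FALSE]
    keep <- as.character(dw$individuals[dw$id]) %in% split$candidates
    ystar <- corrected_phenotype(dw, solw)[keep]
    yhat <- predict_observation(solp, as.character(split$whole$id)[keep],
                                spec = spec)
    pa <- predictive_ability(ystar, yhat)
    out[[i]] <- list(method_r = mr, predictive_ability = pa,
                     n_candidate_records = nrow(cand_rec))
  }
  structure(list(models = out, split = split, variances = used_vars),
            class = "validation_report_set")
}

#' @export
print.validation_report_set <- function(x, ...) {
  print(x$split)
  for (nm in names(x$models)) {
    cat("model ", nm, ":\n  ", sep = "")
    print(x$models[[nm]]$method_r)
    cat("  ")
    print(x$models[[nm]]$predictive_ability)
  }
  invisible(x)
}

#' Run a configured experiment end-to-end
#'
#' Accepts a configuration list (or a YAML file path when the `yaml`
#' package is available) describing a simulation scenario, the model
#' ladder, the chain, and which stages to run, and executes the nested
#' model comparison, the inbreeding contrast and the forward validation.
#'
#' @param config list or YAML path with (all optional) entries
#'   `simulation` (overrides for [sim_config()]), `seed`, `chain`
#'   (`n_iter`, `burn_in`, `thin`), `models`, `cutoff`, and logical stage
#'   switches `nested`, `inbreeding_contrast`, `validation`.
#' @return List of class `experiment_report` with the stage reports and
#'   provenance (seed, config echo).
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  sim_args <- if (is.null(config$simulation)) list() else config$simulation
  sim_args$seed <- seed
  cfg_sim <- do.call(sim_config, sim_args)
  data <- simulate_dataset(cfg_sim)
  ch <- config$chain
  cfg_chain <- chain_config(
    n_iter = if (is.null(ch$n_iter)) 20000 else ch$n_iter,
    burn_in = if (is.null(ch$burn_in)) 2000 else ch$burn_in,
    thin = if (is.null(ch$thin)) 10 else ch$thin,
    seed = seed)
  models <- if (is.null(config$models)) {
    list("A", c("A", "D"), c("A", "D", "AA"), c("A", "D", "AA", "AD"),
         c("A", "D", "AA", "AD", "DD"))
  } else {
    config$models
  }
  grms <- build_grms(data$genotypes,
                     components = unique(unlist(c(models,
                                                  list(c("A", "D", "AA",
                                                         "AD", "DD"))))))
  report <- list(seed = seed, config = config)
  if (!isFALSE(config$nested)) {
    report$nested <- run_nested_models(data$genotypes, data$records,
                                       models = models, cfg = cfg_chain,
                                       grms = grms)
  }
  if (!isFALSE(config$inbreeding_contrast)) {
    report$inbreeding_contrast <- run_inbreeding_contrast(
      data$genotypes, data$records, cfg = cfg_chain, grms = grms)
  }
  if (!isFALSE(config$validation)) {
    cutoff <- if (is.null(config$cutoff)) {
      cfg_sim$n_periods_early + 1
    } else {
      config$cutoff
    }
    vars <- lapply(report$nested$summaries, function(s) {
      stats::setNames(s$components$mean, s$components$component)
    })
    report$validation <- run_validation(
      data$genotypes, data$records, cutoff = cutoff,
      models = list("A", c("A", "D"), c("A", "D", "AA", "AD", "DD")),
      variances = if (length(vars)) vars else NULL,
      cfg = cfg_chain, grms = grms)
  }
  report$data <- data
  class(report) <- "experiment_report"
  report
}
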