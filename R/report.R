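# Command layer: validated run configurations, artifact writers and run
# manifests. Each cmd_* function is also exposed as a subcommand of the
# bundled command-line script (inst/cli/priorelicit).

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) pe_stop("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    pe_stop("config must be .yaml/.yml or .json (got .%s)", ext)
  }
}

config_field <- function(config, field, default = NULL, required = is.null(default)) {
  v <- config[[field]]
  if (is.null(v)) {
    if (required) pe_stop("config: missing required field '%s'", field)
    return(default)
  }
  v
}

config_path <- function(config, field) {
  p <- config_field(config, field)
  if (!file.exists(p)) pe_stop("config: '%s' path does not exist: %s", field, p)
  p
}

builtin_problem <- function(name) {
  switch(name,
         heart = heart_disease_problem(),
         concrete = concrete_strength_problem(),
         pe_stop("config: unknown problem '%s' (use 'heart' or 'concrete')", name))
}

builtin_spec <- function(name, seed) {
  switch(name,
         heart = heart_like_spec(seed = seed),
         concrete = concrete_like_spec(seed = seed),
         pe_stop("config: unknown spec '%s' (use 'heart' or 'concrete')", name))
}

# Shared command wrapper: runs `body` (which returns a named list of output
# paths), removes partial outputs on failure, and writes a manifest with the
# config echo, seed, package version and input hashes.
run_command <- function(command, config, input_paths, body) {
  out_dir <- config_field(config, "output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  before <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  res <- tryCatch(body(), error = function(e) {
    after <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
    partial <- setdiff(after, before)
    if (length(partial)) unlink(partial)
    pe_stop("%s: %s", command, conditionMessage(e))
  })
  manifest <- list(
    command = command,
    config = config,
    seed = config_field(config, "seed", default = NA),
    package_version = as.character(utils::packageVersion("priorelicit")),
    input_hashes = if (length(input_paths)) {
      as.list(stats::setNames(vapply(input_paths, hash_file, character(1)),
                              basename(input_paths)))
    } else list(),
    outputs = as.list(basename(unlist(res)))
  )
  manifest_path <- file.path(out_dir, paste0(command, "_manifest.json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), manifest_path)
  invisible(c(unlist(res), manifest = manifest_path))
}

#' Command: generate a synthetic dataset
#'
#' Config fields: `spec` (`"heart"` or `"concrete"`), `seed`, `output_dir`,
#' optional `n`.
#'
#' @param config a list or a path to a YAML/JSON file.
#' @return output paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config_field(config, "seed")
  spec <- builtin_spec(config_field(config, "spec"), seed = seed)
  if (!is.null(config$n)) spec$n <- as.integer(config$n)
  out_dir <- config_field(config, "output_dir")
  run_command("simulate", config, character(), function() {
    data <- generate(spec)
    path <- file.path(out_dir, "dataset.csv")
    write_regression_data(data, path)
    list(dataset = path)
  })
}

#' Command: write the elicitation prompt for a problem
#'
#' Config fields: `problem` (`"heart"` or `"concrete"`), `output_dir`,
#' optional `provider`, `n_sets`.
#'
#' @inheritParams cmd_simulate
#' @return output paths, invisibly.
#' @export
cmd_elicit_prompt <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  problem <- builtin_problem(config_field(config, "problem"))
  opts <- elicitation_options(
    n_sets = config_field(config, "n_sets", default = 2),
    provider = config$provider)
  out_dir <- config_field(config, "output_dir")
  run_command("elicit-prompt", config, character(), function() {
    prompt <- build_prompt(problem, opts)
    path <- file.path(out_dir, "prompt.txt")
    writeLines(prompt$text, path)
    list(prompt = path)
  })
}

#' Command: parse a recorded response into a validated prior document
#'
#' Config fields: `response` (path to the raw response text), `output_dir`.
#'
#' @inheritParams cmd_simulate
#' @return output paths, invisibly.
#' @export
cmd_parse_response <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  response_path <- config_path(config, "response")
  out_dir <- config_field(config, "output_dir")
  run_command("parse-response", config, response_path, function() {
    doc <- extract_prior_document(paste(readLines(response_path, warn = FALSE),
                                        collapse = "\n"))
    path <- file.path(out_dir, "priors.json")
    write_prior_document(doc, path)
    list(priors = path)
  })
}

#' Command: score a prior document against a fitted dataset
#'
#' Config fields: `dataset` (delimited file), `response` (response column
#' name), `family`, `priors` (prior document path), `output_dir`; optional
#' `bootstrap` (logical), `B`, `seed`.
#'
#' @inheritParams cmd_simulate
#' @return output paths, invisibly.
#' @export
cmd_evaluate_priors <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dataset_path <- config_path(config, "dataset")
  priors_path <- config_path(config, "priors")
  family <- match.arg(config_field(config, "family"), c("logistic", "linear"))
  out_dir <- config_field(config, "output_dir")
  run_command("evaluate-priors", config, c(dataset_path, priors_path), function() {
    data <- read_regression_data(dataset_path,
                                 response = config_field(config, "response", default = "y"))
    doc <- align_to_problem(read_prior_document(priors_path), data$variable_names)
    mle <- if (isTRUE(config$bootstrap)) {
      bootstrap_mle(data, family, B = config_field(config, "B", default = 1000),
                    seed = config_field(config, "seed", default = 1))
    } else {
      fit_mle(data, family)
    }
    report <- kl_table(mle, doc)
    stem <- file.path(out_dir, "kl_report")
    paths <- write_kl_report(report, stem)
    list(table = paths[1], json = paths[2])
  })
}

#' Command: fit posterior approximations for every set of a document
#'
#' Config fields: `dataset`, `response`, `family`, `priors`, `output_dir`;
#' optional `plots` (logical) to render overlay grids per set.
#'
#' @inheritParams cmd_simulate
#' @return output paths, invisibly.
#' @export
cmd_fit_posterior <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dataset_path <- config_path(config, "dataset")
  priors_path <- config_path(config, "priors")
  family <- match.arg(config_field(config, "family"), c("logistic", "linear"))
  out_dir <- config_field(config, "output_dir")
  run_command("fit-posterior", config, c(dataset_path, priors_path), function() {
    data <- read_regression_data(dataset_path,
                                 response = config_field(config, "response", default = "y"))
    doc <- align_to_problem(read_prior_document(priors_path), data$variable_names)
    mle <- fit_mle(data, family)
    outputs <- list()
    for (s in doc$sets) {
      post <- laplace_posterior(data, family, s)
      safe <- gsub("[^A-Za-z0-9_.-]", "_", s$label)
      path <- file.path(out_dir, paste0("posterior_", safe, ".json"))
      payload <- list(set = s$label, method = post$method,
                      mode = as.list(post$mode),
                      sd = as.list(stats::setNames(sqrt(diag(post$cov)),
                                                   names(post$mode))),
                      cov = apply(post$cov, 1, as.list))
      writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), path)
      outputs[[paste0("posterior_", safe)]] <- path
      if (isTRUE(config$plots)) {
        ppath <- file.path(out_dir, paste0("overlay_", safe, ".png"))
        plot_overlay_grid(mle, s, posterior = post, file = ppath)
        outputs[[paste0("overlay_", safe)]] <- ppath
      }
    }
    outputs
  })
}

#' Command: cross-validated predictive comparison against the frequentist fit
#'
#' Config fields: `dataset`, `response`, `family`, `priors` (one or more
#' prior document paths), `output_dir`; optional `K` (default 5), `seed`.
#'
#' @inheritParams cmd_simulate
#' @return output paths, invisibly.
#' @export
cmd_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dataset_path <- config_path(config, "dataset")
  priors_paths <- config_field(config, "priors")
  for (p in priors_paths) if (!file.exists(p)) {
    pe_stop("config: priors path does not exist: %s", p)
  }
  family <- match.arg(config_field(config, "family"), c("logistic", "linear"))
  out_dir <- config_field(config, "output_dir")
  run_command("compare", config, c(dataset_path, priors_paths), function() {
    data <- read_regression_data(dataset_path,
                                 response = config_field(config, "response", default = "y"))
    models <- list(Frequentist = cv_model_frequentist())
    for (p in priors_paths) {
      doc <- align_to_problem(read_prior_document(p), data$variable_names)
      models <- c(models, cv_models_from_document(doc))
    }
    cv <- kfold_cv(data, models, family,
                   K = config_field(config, "K", default = 5),
                   seed = config_field(config, "seed", default = 1))
    report <- compare_models(cv, baseline = "Frequentist")
    stem <- file.path(out_dir, "comparison")
    paths <- write_comparison_report(report, stem)
    list(table = paths[1], json = paths[2])
  })
}
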