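#' Define a regression problem for elicitation
#'
#' The model specification communicated to the language model: what is being
#' predicted, with which covariates, on which units, under which regression
#' family. Variable descriptions and typical ranges give the model the
#' context it needs to translate domain knowledge (odds ratios, effect sizes)
#' into coefficient-scale priors.
#'
#' @param name short problem name.
#' @param response list with elements `name`, `description`,
#'   `kind` (`"binary"` or `"continuous"`) and `unit`.
#' @param family `"logistic"` or `"linear"`; must be consistent with the
#'   response kind (logistic/binary, linear/continuous).
#' @param variables data frame with columns `name`, `description`, `unit` and
#'   optionally `range` (free-text typical range), one row per covariate in
#'   model order.
#' @param n_samples optional number of samples in the study data.
#' @return an object of class `regression_problem`.
#' @export
regression_problem <- function(name, response, family = c("logistic", "linear"),
                               variables, n_samples = NULL) {
  family <- match.arg(family)
  if (!is.character(name) || length(name) != 1L) {
    pe_stop("regression_problem: 'name' must be a string")
  }
  for (f in c("name", "description", "kind", "unit")) {
    if (is.null(response[[f]])) {
      pe_stop("regression_problem: response is missing '%s'", f)
    }
  }
  if (!response$kind %in% c("binary", "continuous")) {
    pe_stop("regression_problem: response kind must be 'binary' or 'continuous'")
  }
  consistent <- (family == "logistic" && response$kind == "binary") ||
    (family == "linear" && response$kind == "continuous")
  if (!consistent) {
    pe_stop("regression_problem: family '%s' inconsistent with response kind '%s'",
            family, response$kind)
  }
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  if (nrow(variables) < 1L) {
    pe_stop("regression_problem: at least one variable is required")
  }
  for (col in c("name", "description", "unit")) {
    if (is.null(variables[[col]])) {
      pe_stop("regression_problem: variables need a '%s' column", col)
    }
  }
  if (is.null(variables$range)) variables$range <- NA_character_
  if (anyDuplicated(variables$name)) {
    pe_stop("regression_problem: duplicate variable name(s): %s",
            paste(unique(variables$name[duplicated(variables$name)]), collapse = ", "))
  }
  structure(list(name = name, response = response, family = family,
                 variables = variables,
                 n_samples = if (is.null(n_samples)) NA_integer_ else as.integer(n_samples)),
            class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf("<regression_problem> '%s': %s regression of %s (%s) on %d variable(s)\n",
              x$name, x$family, x$response$name, x$response$kind,
              nrow(x$variables)))
  invisible(x)
}

#' Variable names of a regression problem
#' @param problem a [regression_problem()].
#' @return character vector of covariate names in model order.
#' @export
problem_variables <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  problem$variables$name
}

#' Built-in problem: coronary artery disease risk
#'
#' Logistic regression of the presence of coronary artery disease on the five
#' continuous patient characteristics plus sex used in the Cleveland
#' heart-disease case study (303 patients, 46% prevalence).
#'
#' @return a [regression_problem()].
#' @export
heart_disease_problem <- function() {
  regression_problem(
    name = "heart-disease",
    response = list(name = "cad",
                    description = "presence of coronary artery disease (1 = present, 0 = absent)",
                    kind = "binary", unit = "dimensionless"),
    family = "logistic",
    variables = data.frame(
      name = c("age", "sex", "trestbps", "chol", "thalach", "oldpeak"),
      description = c("Age of the individual",
                      "Biological sex (binary, male = 1, female = 0)",
                      "Resting blood pressure on admission",
                      "Serum cholesterol level",
                      "Maximum heart rate achieved",
                      "ST depression induced by exercise relative to rest"),
      unit = c("years", "dimensionless", "mmHg", "mg/dl",
               "beats per minute", "mm"),
      range = c("29-77", "0 or 1", "94-200", "126-564", "71-202", "0-6.2"),
      stringsAsFactors = FALSE
    ),
    n_samples = 303
  )
}

#' Built-in problem: concrete compressive strength
#'
#' Multiple linear regression of concrete compressive strength (MPa) on the
#' mixture components and curing age (1030 samples).
#'
#' @return a [regression_problem()].
#' @export
concrete_strength_problem <- function() {
  regression_problem(
    name = "concrete-compressive-strength",
    response = list(name = "ccs",
                    description = "compressive strength of the concrete sample",
                    kind = "continuous", unit = "MPa"),
    family = "linear",
    variables = data.frame(
      name = c("Age", "Cement", "Blast Furnace Slag", "Fly Ash", "Water",
               "Superplasticizer", "Coarse Aggregate", "Fine Aggregate"),
      description = c("Curing time", "Binder", "Cement replacement",
                      "Cement replacement", "Activates cement",
                      "Water reducer", "Filler, strength",
                      "Filler, workability"),
      unit = c("day", rep("kg/m^3", 7)),
      range = c("1-365", "102-540", "0-359", "0-200", "122-247", "0-32",
                "801-1145", "594-993"),
      stringsAsFactors = FALSE
    ),
    n_samples = 1030
  )
}

#' Options controlling prompt construction
#'
#' @param n_sets minimum number of prior sets to request (default 2:
#'   moderately and weakly informative).
#' @param set_labels labels the model is asked to use for the sets.
#' @param provider optional provider tag recorded in the prompt header, so
#'   transcripts for different models hash differently.
#' @param extra_context optional extra free text appended to the role section.
#' @return a list of class `elicitation_options`.
#' @export
elicitation_options <- function(n_sets = 2,
                                set_labels = c("moderately informative",
                                               "weakly informative"),
                                provider = NULL,
                                extra_context = NULL) {
  if (!is_scalar_number(n_sets) || n_sets < 1) {
    pe_stop("elicitation_options: n_sets must be >= 1")
  }
  structure(list(n_sets = as.integer(n_sets),
                 set_labels = as.character(set_labels),
                 provider = provider,
                 extra_context = extra_context),
            class = "elicitation_options")
}

prompt_schema_skeleton <- function(problem) {
  v1 <- problem$variables$name[1]
  paste0(
    "{\n",
    '  "problem_name": "', problem$name, '",\n',
    '  "provenance": "<your model name>",\n',
    '  "sets": [\n',
    "    {\n",
    '      "label": "<set label>",\n',
    '      "informativeness": "moderate | weak | custom",\n',
    '      "confidence_weight": 0.0,\n',
    '      "entries": {\n',
    '        "', v1, '": {"mean": 0.0, "sd": 1.0, ',
    '"justification": "<why>", "sources": ["<source>"]}\n',
    "      }\n",
    "    }\n",
    "  ]\n",
    "}"
  )
}

#' Build the structured elicitation prompt
#'
#' Assembles the five-section prompt sent to a language model: role/context,
#' data description, model and prior-family statement, instruction block and
#' required machine-readable output format. The construction is a pure
#' function of its arguments: identical inputs give byte-identical text.
#'
#' @param problem a [regression_problem()].
#' @param options an [elicitation_options()].
#' @return an object of class `elicitation_prompt` with elements `sections`
#'   (named list of the five section texts) and `text` (the full prompt).
#' @export
build_prompt <- function(problem, options = elicitation_options()) {
  stopifnot(inherits(problem, "regression_problem"))
  if (!inherits(options, "elicitation_options")) {
    pe_stop("build_prompt: 'options' must come from elicitation_options()")
  }
  if (nrow(problem$variables) < 1L) {
    pe_stop("build_prompt: the problem has no variables")
  }
  resp <- problem$response
  coef_scale <- if (problem$family == "logistic") {
    "log-odds of the response per unit of the covariate (convert any known odds ratios or linear associations into log-odds)"
  } else {
    sprintf("change in the response (%s) per unit of the covariate", resp$unit)
  }

  role <- paste0(
    "You are a careful domain expert assisting a Bayesian regression analysis. ",
    "Use your absorbed knowledge of the relevant scientific literature to propose ",
    "informative prior distributions, and be explicit about your reasoning and its sources.",
    if (!is.null(options$provider)) sprintf("\n[provider: %s]", options$provider) else "",
    if (!is.null(options$extra_context)) paste0("\n", options$extra_context) else ""
  )

  nstr <- if (is.na(problem$n_samples)) "" else sprintf(" The study data comprise %d samples.", problem$n_samples)
  var_lines <- vapply(seq_len(nrow(problem$variables)), function(i) {
    v <- problem$variables[i, ]
    rng <- if (is.na(v$range)) "" else sprintf("; typical range: %s", v$range)
    sprintf("- %s: %s (unit: %s%s)", v$name, v$description, v$unit, rng)
  }, character(1))
  data_desc <- paste0(
    sprintf("Problem: %s.%s\n", problem$name, nstr),
    sprintf("Response: %s - %s (%s, unit: %s).\n", resp$name, resp$description,
            resp$kind, resp$unit),
    "Covariates:\n",
    paste(var_lines, collapse = "\n")
  )

  model_stmt <- paste0(
    sprintf("We fit a %s regression model of the response on the covariates listed above, ",
            problem$family),
    "with an independent Gaussian prior distribution N(mean, sd^2) on each regression coefficient. ",
    "Covariates enter the model on their natural, unstandardized scale, so each coefficient is the ",
    coef_scale, "."
  )

  labels_txt <- paste(options$set_labels, collapse = " and ")
  instructions <- paste0(
    "Instructions:\n",
    "1. For every covariate, propose the mean and sd of its Gaussian coefficient prior, and justify each hyperparameter value.\n",
    "2. Cite the knowledge sources (studies, registries, meta-analyses, textbooks) behind each choice.\n",
    sprintf("3. Propose at least %d sets of priors, labelled %s, reflecting different levels of confidence in your knowledge.\n",
            options$n_sets, labels_txt),
    "4. Assign each set a relative confidence score in [0, 1]; the scores must sum to 1 across sets.\n",
    "5. Before answering, perform a verification and reflection pass: re-check signs, magnitudes and unit conversions, and revise anything inconsistent."
  )

  output_format <- paste0(
    "Required output format: after your reasoning, return EXACTLY ONE fenced ```json code block ",
    "containing a single document with this structure (one entry per covariate in every set):\n",
    "```json\n", prompt_schema_skeleton(problem), "\n```"
  )

  sections <- list(role_context = role,
                   data_description = data_desc,
                   model_statement = model_stmt,
                   instructions = instructions,
                   output_format = output_format)
  text <- paste(unlist(sections), collapse = "\n\n")
  structure(list(sections = sections, text = text, problem_name = problem$name),
            class = "elicitation_prompt")
}

#' @export
print.elicitation_prompt <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Text of an elicitation prompt
#' @param prompt an `elicitation_prompt` (or plain character).
#' @return the prompt text as a single string.
#' @export
prompt_text <- function(prompt) {
  if (inherits(prompt, "elicitation_prompt")) prompt$text else
    paste(as.character(prompt), collapse = "\n")
}

#' Stable hash of a prompt
#'
#' Used to key recorded responses in replay transports.
#'
#' @param prompt an `elicitation_prompt` or character text.
#' @return a hexadecimal hash string.
#' @export
prompt_hash <- function(prompt) {
  hash_text(prompt_text(prompt))
}

# ---- transports ------------------------------------------------------------

replay_index_path <- function(dir) file.path(dir, "index.json")

read_replay_index <- function(dir) {
  path <- replay_index_path(dir)
  if (!file.exists(path)) {
    pe_stop("replay transport: no index.json in %s", dir)
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Deterministic replay transport for recorded responses
#'
#' A transport that answers prompts from a directory of recorded response
#' files, keyed by prompt hash through an `index.json`. Replay is fully
#' deterministic: the same prompt always yields the byte-identical recorded
#' text, and unknown prompts fail loudly with their hash.
#'
#' @param dir directory holding `index.json` and the response files.
#' @param fixture optional fixture id to disambiguate when several recordings
#'   exist for the same prompt.
#' @return a transport object (class `replay_transport`).
#' @seealso [record_response()], [bundled_replay_dir()]
#' @export
replay_transport <- function(dir, fixture = NULL) {
  if (!dir.exists(dir)) pe_stop("replay transport: directory not found: %s", dir)
  structure(list(mode = "replay", dir = dir, fixture = fixture),
            class = c("replay_transport", "elicitation_transport"))
}

#' Live transport backed by a user-supplied send function
#'
#' Wraps any function `send(prompt_text) -> response_text` (an API client,
#' say) as a transport. Failures of `send` are surfaced, never masked; no
#' retry policy is imposed.
#'
#' @param send function taking the prompt text and returning the response text.
#' @param provenance free text recorded with every response.
#' @return a transport object (class `live_transport`).
#' @export
live_transport <- function(send, provenance = "live") {
  if (!is.function(send)) pe_stop("live_transport: 'send' must be a function")
  structure(list(mode = "live", send = send, provenance = provenance),
            class = c("live_transport", "elicitation_transport"))
}

transport_send <- function(transport, prompt) UseMethod("transport_send")

#' @export
transport_send.replay_transport <- function(transport, prompt) {
  h <- prompt_hash(prompt)
  index <- read_replay_index(transport$dir)
  hits <- Filter(function(rec) identical(rec$prompt_hash, h), index)
  if (!is.null(transport$fixture)) {
    hits <- Filter(function(rec) identical(rec$id, transport$fixture), hits)
  }
  if (length(hits) == 0L) {
    pe_stop("replay miss: no recorded response for prompt hash %s%s", h,
            if (is.null(transport$fixture)) "" else
              sprintf(" (fixture '%s')", transport$fixture))
  }
  rec <- hits[[1]]
  path <- file.path(transport$dir, rec$file)
  if (!file.exists(path)) {
    pe_stop("replay transport: index names missing file %s", rec$file)
  }
  list(text = paste(readLines(path, warn = FALSE), collapse = "\n"),
       provenance = if (is.null(rec$provenance)) rec$id else rec$provenance)
}

#' @export
transport_send.live_transport <- function(transport, prompt) {
  text <- tryCatch(transport$send(prompt_text(prompt)), error = function(e) {
    pe_stop("live transport failure: %s", conditionMessage(e))
  })
  list(text = as.character(text), provenance = transport$provenance)
}

#' Record a response into a replay directory
#'
#' Writes the response text and registers it in the directory's `index.json`
#' under the prompt's hash, creating the directory and index as needed.
#'
#' @param dir replay directory.
#' @param prompt the prompt the response answers.
#' @param response response text (character, possibly multi-line).
#' @param id fixture id (also used as the response file name).
#' @param provenance free text identifying the responder.
#' @return the replay directory, invisibly.
#' @export
record_response <- function(dir, prompt, response, id, provenance = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fname <- paste0(id, ".txt")
  writeLines(paste(response, collapse = "\n"), file.path(dir, fname))
  idx_path <- replay_index_path(dir)
  index <- if (file.exists(idx_path)) {
    jsonlite::fromJSON(idx_path, simplifyVector = FALSE)
  } else list()
  index <- Filter(function(rec) !identical(rec$id, id), index)
  index <- c(index, list(list(id = id, prompt_hash = prompt_hash(prompt),
                              file = fname, provenance = provenance)))
  writeLines(jsonlite::toJSON(index, auto_unbox = TRUE, pretty = TRUE), idx_path)
  invisible(dir)
}

#' Directory of replay fixtures bundled with the package
#'
#' The bundled recordings are synthetic stand-ins for elicitation
#' transcripts: their confidence weights and the heart-disease sex prior
#' N(0.7, 0.3) match reported elicitation outcomes, while all other
#' hyperparameters are fixture-invented values on plausible scales.
#'
#' @return path to the bundled replay directory.
#' @export
bundled_replay_dir <- function() {
  system.file("extdata", "replay", package = "priorelicit", mustWork = TRUE)
}

#' Obtain a response for a prompt through a transport
#'
#' Returns the transport's response verbatim together with the prompt hash
#' and provenance, forming an auditable record of the exchange.
#'
#' @param prompt an `elicitation_prompt`.
#' @param transport a transport from [replay_transport()] or
#'   [live_transport()].
#' @return an object of class `elicitation_record` with elements `response`,
#'   `prompt_hash`, `provenance` and `mode`.
#' @export
elicit <- function(prompt, transport) {
  if (!inherits(transport, "elicitation_transport")) {
    pe_stop("elicit: 'transport' must be a configured transport object")
  }
  res <- transport_send(transport, prompt)
  rec <- structure(list(response = res$text,
                        prompt_hash = prompt_hash(prompt),
                        provenance = res$provenance,
                        mode = transport$mode),
                   class = "elicitation_record")
  if (isTRUE(getOption("priorelicit.verbose", FALSE))) {
    message(sprintf("elicit: mode=%s hash=%s provenance=%s",
                    rec$mode, rec$prompt_hash, rec$provenance))
  }
  rec
}

#' @export
print.elicitation_record <- function(x, ...) {
  cat(sprintf("<elicitation_record> mode=%s hash=%s provenance=%s (%d chars)\n",
              x$mode, x$prompt_hash, x$provenance, nchar(x$response)))
  invisible(x)
}

#' Extract the structured prior document from a raw response
#'
#' The elicitation contract requires the model to return exactly one fenced
#' ```` ```json ```` block with the prior document; anything else (prose-only
#' answers, several blocks) is rejected rather than guessed at.
#'
#' @param response an [elicit()] record or raw response text.
#' @return a validated [prior_document()]; the record's provenance replaces
#'   the document's when the document carries none.
#' @export
extract_prior_document <- function(response) {
  provenance <- ""
  if (inherits(response, "elicitation_record")) {
    provenance <- response$provenance
    response <- response$response
  }
  text <- paste(as.character(response), collapse = "\n")
  m <- gregexpr("(?s)```json\\s*\\n(.*?)```", text, perl = TRUE)[[1]]
  n_blocks <- if (m[1] == -1L) 0L else length(m)
  if (n_blocks != 1L) {
    pe_stop("extract_prior_document: expected exactly one ```json document block, found %d",
            n_blocks)
  }
  block <- regmatches(text, m)[1]
  inner <- sub("^```json\\s*\\n", "", block)
  inner <- sub("```\\s*$", "", inner)
  doc <- parse_prior_document(inner)
  if (!nzchar(doc$provenance) && nzchar(provenance)) {
    doc$provenance <- provenance
  }
  doc
}
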