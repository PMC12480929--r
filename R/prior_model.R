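#' Univariate Gaussian distribution
#'
#' The elementary container of the package: a single Gaussian `N(mean, sd^2)`.
#' It represents both a prior marginal for one regression coefficient and the
#' Gaussian approximation of the maximum-likelihood estimator's marginal
#' sampling distribution. For logistic models the units are log-odds per unit
#' of the covariate on its natural scale; for linear models, response units
#' per covariate unit.
#'
#' @param mean finite real; location.
#' @param sd finite real, strictly positive; scale (same units as `mean`).
#' @return an object of class `gaussian1d`.
#' @export
#' @examples
#' gaussian1d(0.7, 0.3)
gaussian1d <- function(mean, sd) {
  if (!is_scalar_number(mean) || !is.finite(mean)) {
    pe_stop("gaussian1d: 'mean' must be a finite number")
  }
  if (!is_scalar_number(sd) || !is.finite(sd)) {
    pe_stop("gaussian1d: 'sd' must be a finite number")
  }
  if (sd <= 0) {
    pe_stop("gaussian1d: 'sd' must be strictly positive (got %g)", sd)
  }
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "gaussian1d")
}

#' @export
format.gaussian1d <- function(x, ...) {
  sprintf("N(%g, %g)", x$mean, x$sd)
}

#' @export
print.gaussian1d <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Convert an odds ratio to the log-odds scale
#'
#' Logistic-regression coefficients live on the log-odds scale, while domain
#' knowledge (risk of disease for males vs females, say) is usually stated as
#' an odds ratio. `or_to_log_odds(2)` is `log(2) ~ 0.7`: a doubling of the
#' odds per unit of the covariate.
#'
#' @param odds_ratio strictly positive odds ratio.
#' @return the natural logarithm of `odds_ratio`.
#' @export
#' @examples
#' or_to_log_odds(2)    # ~0.693
#' or_to_log_odds(1)    # no effect -> 0
or_to_log_odds <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio))) {
    pe_stop("or_to_log_odds: 'odds_ratio' must be finite and numeric")
  }
  if (any(odds_ratio <= 0)) {
    pe_stop("or_to_log_odds: odds ratios must be strictly positive")
  }
  log(odds_ratio)
}

#' Single prior entry for one variable
#'
#' @param mean,sd hyperparameters of the Gaussian prior (see [gaussian1d()]).
#' @param justification free-text reasoning behind the hyperparameters; never
#'   interpreted computationally.
#' @param sources character vector of knowledge sources cited for the entry.
#' @return a list with elements `prior`, `justification`, `sources`.
#' @export
prior_entry <- function(mean, sd, justification = "", sources = character()) {
  list(prior = gaussian1d(mean, sd),
       justification = as.character(justification)[1],
       sources = as.character(sources))
}

#' A named, weighted set of per-variable Gaussian priors
#'
#' One elicited prior set (e.g. the "moderately informative" suggestion of a
#' model), holding an independent Gaussian prior per regression coefficient
#' together with the free-text justification and sources attached to each.
#'
#' @param label display label, unique within a document (e.g. `"Claude_Weak"`).
#' @param informativeness one of `"weak"`, `"moderate"`, `"custom"`.
#' @param confidence_weight relative confidence in this set, in `[0, 1]`;
#'   weights of all sets in a document sum to 1.
#' @param entries named list, variable name -> [prior_entry()] (a bare
#'   [gaussian1d()] is accepted and wrapped).
#' @return an object of class `prior_set`.
#' @export
prior_set <- function(label,
                      informativeness = c("weak", "moderate", "custom"),
                      confidence_weight,
                      entries = list()) {
  informativeness <- match.arg(informativeness)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    pe_stop("prior_set: 'label' must be a non-empty string")
  }
  if (!is_scalar_number(confidence_weight) ||
      confidence_weight < 0 || confidence_weight > 1) {
    pe_stop("prior_set '%s': confidence_weight must lie in [0, 1]", label)
  }
  if (length(entries) > 0) {
    nm <- names(entries)
    if (is.null(nm) || any(!nzchar(nm))) {
      pe_stop("prior_set '%s': all entries must be named by variable", label)
    }
    if (anyDuplicated(nm)) {
      pe_stop("prior_set '%s': duplicate variable name(s): %s", label,
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
    }
    entries <- lapply(entries, function(e) {
      if (inherits(e, "gaussian1d")) e <- list(prior = e)
      if (!is.list(e) || !inherits(e$prior, "gaussian1d")) {
        pe_stop("prior_set '%s': each entry needs a gaussian1d 'prior'", label)
      }
      list(prior = e$prior,
           justification = if (is.null(e$justification)) "" else as.character(e$justification)[1],
           sources = if (is.null(e$sources)) character() else as.character(e$sources))
    })
    names(entries) <- nm
  }
  structure(list(label = label,
                 informativeness = informativeness,
                 confidence_weight = as.numeric(confidence_weight),
                 entries = entries),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("<prior_set> %s (%s, weight %.2f), %d entries\n",
              x$label, x$informativeness, x$confidence_weight,
              length(x$entries)))
  for (v in names(x$entries)) {
    cat(sprintf("  %-20s %s\n", v, format(x$entries[[v]]$prior)))
  }
  invisible(x)
}

# tolerance on the sum of confidence weights across sets
WEIGHT_TOL <- 0.01

#' A document of elicited prior sets for one regression problem
#'
#' @param problem_name name of the regression problem the priors address.
#' @param sets list of [prior_set()]; at least one, labels unique, confidence
#'   weights summing to 1 within 0.01.
#' @param provenance free text identifying where the priors came from (model
#'   name, transcript id).
#' @return an object of class `prior_document`.
#' @export
prior_document <- function(problem_name, sets, provenance = "") {
  if (!is.character(problem_name) || length(problem_name) != 1L) {
    pe_stop("prior_document: 'problem_name' must be a string")
  }
  if (!is.list(sets) || length(sets) < 1L ||
      !all(vapply(sets, inherits, logical(1), "prior_set"))) {
    pe_stop("prior_document: 'sets' must be a non-empty list of prior_set objects")
  }
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    pe_stop("prior_document: duplicate set label(s): %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  wsum <- sum(vapply(sets, `[[`, numeric(1), "confidence_weight"))
  if (abs(wsum - 1) > WEIGHT_TOL) {
    pe_stop("prior_document: confidence weights sum to %.4f, expected 1 within %.2f",
            wsum, WEIGHT_TOL)
  }
  names(sets) <- labels
  structure(list(problem_name = problem_name,
                 sets = sets,
                 provenance = as.character(provenance)[1]),
            class = "prior_document")
}

#' @export
print.prior_document <- function(x, ...) {
  cat(sprintf("<prior_document> '%s' (%s): %d set(s)\n", x$problem_name,
              if (nzchar(x$provenance)) x$provenance else "no provenance",
              length(x$sets)))
  for (s in x$sets) {
    cat(sprintf("  %-24s %-8s weight %.2f  (%d entries)\n",
                s$label, s$informativeness, s$confidence_weight,
                length(s$entries)))
  }
  invisible(x)
}

#' Set labels of a prior document
#' @param doc a [prior_document()].
#' @return character vector of set labels, in document order.
#' @export
set_labels <- function(doc) {
  stopifnot(inherits(doc, "prior_document"))
  vapply(doc$sets, `[[`, character(1), "label")
}

# ---- serialization ---------------------------------------------------------

prior_document_to_list <- function(doc) {
  list(
    problem_name = doc$problem_name,
    provenance = doc$provenance,
    sets = lapply(unname(doc$sets), function(s) {
      list(
        label = s$label,
        informativeness = s$informativeness,
        confidence_weight = s$confidence_weight,
        entries = lapply(s$entries, function(e) {
          list(mean = e$prior$mean, sd = e$prior$sd,
               justification = e$justification,
               sources = as.list(e$sources))
        })
      )
    })
  )
}

#' Serialize a prior document to JSON
#'
#' The inverse of [parse_prior_document()]: numbers are written at full
#' precision so that parse -> serialize -> parse is the identity.
#'
#' @param doc a [prior_document()].
#' @param path optional file to write to; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when `path` is given.
#' @export
write_prior_document <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "prior_document"))
  json <- jsonlite::toJSON(prior_document_to_list(doc),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

need_field <- function(x, field, path) {
  if (is.null(x[[field]])) {
    pe_stop("prior document: missing required field at %s.%s", path, field)
  }
  x[[field]]
}

need_number <- function(x, field, path) {
  v <- need_field(x, field, path)
  if (!is_scalar_number(v)) {
    pe_stop("prior document: %s.%s must be a number", path, field)
  }
  as.numeric(v)
}

#' Parse a structured prior document
#'
#' Reads the JSON interchange format for elicited priors (see
#' [prior_document_schema_path()] for the published schema). All
#' [prior_document()] invariants are enforced; violations raise errors naming
#' the offending path within the document.
#'
#' @param text a JSON string (or character vector of lines) containing one
#'   prior document.
#' @return a validated [prior_document()].
#' @export
parse_prior_document <- function(text) {
  raw <- tryCatch(
    jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE),
    error = function(e) pe_stop("prior document: invalid JSON: %s", conditionMessage(e))
  )
  if (!is.list(raw)) pe_stop("prior document: top level must be an object")
  problem_name <- need_field(raw, "problem_name", "$")
  sets_raw <- need_field(raw, "sets", "$")
  if (!is.list(sets_raw) || length(sets_raw) < 1L) {
    pe_stop("prior document: $.sets must be a non-empty array")
  }
  sets <- vector("list", length(sets_raw))
  for (i in seq_along(sets_raw)) {
    s <- sets_raw[[i]]
    spath <- sprintf("$.sets[%d]", i)
    label <- as.character(need_field(s, "label", spath))
    informativeness <- as.character(need_field(s, "informativeness", spath))
    if (!informativeness %in% c("weak", "moderate", "custom")) {
      pe_stop("prior document: %s.informativeness must be weak/moderate/custom", spath)
    }
    weight <- need_number(s, "confidence_weight", spath)
    entries_raw <- need_field(s, "entries", spath)
    if (!is.list(entries_raw) || is.null(names(entries_raw))) {
      pe_stop("prior document: %s.entries must be an object keyed by variable", spath)
    }
    if (anyDuplicated(names(entries_raw))) {
      dup <- unique(names(entries_raw)[duplicated(names(entries_raw))])
      pe_stop("prior document: duplicate variable '%s' in %s.entries", dup[1], spath)
    }
    entries <- lapply(seq_along(entries_raw), function(j) {
      v <- names(entries_raw)[j]
      e <- entries_raw[[j]]
      epath <- sprintf("%s.entries.%s", spath, v)
      m <- need_number(e, "mean", epath)
      sd <- need_number(e, "sd", epath)
      if (!is.finite(sd) || sd <= 0) {
        pe_stop("prior document: %s.sd must be strictly positive (got %g)", epath, sd)
      }
      prior_entry(m, sd,
                  justification = if (is.null(e$justification)) "" else e$justification,
                  sources = if (is.null(e$sources)) character() else unlist(e$sources))
    })
    names(entries) <- names(entries_raw)
    sets[[i]] <- prior_set(label, informativeness, weight, entries)
  }
  prior_document(problem_name, sets,
                 provenance = if (is.null(raw$provenance)) "" else raw$provenance)
}

#' Read a prior document from a file
#' @param path path to a JSON prior document.
#' @return a validated [prior_document()].
#' @export
read_prior_document <- function(path) {
  if (!file.exists(path)) pe_stop("prior document file not found: %s", path)
  parse_prior_document(readLines(path, warn = FALSE))
}

#' Path to the published JSON schema for prior documents
#' @return path to the schema file shipped with the package.
#' @export
prior_document_schema_path <- function() {
  system.file("schema", "prior-document.schema.json", package = "priorelicit",
              mustWork = TRUE)
}

# shared alignment check between a set of entry names and problem variables
check_alignment <- function(have, want, label) {
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) > 0) {
    pe_stop("prior set '%s' is missing variable(s): %s", label,
            paste(missing, collapse = ", "))
  }
  if (length(extra) > 0) {
    pe_stop("prior set '%s' has extra variable(s) not in the problem: %s",
            label, paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Align a prior document to a regression problem
#'
#' Verifies that every set covers exactly the problem's variables and reorders
#' each set's entries to the problem's variable order. Missing or extra
#' variables are errors (nothing is dropped silently).
#'
#' @param doc a [prior_document()].
#' @param problem a [regression_problem()] or a character vector of variable
#'   names in the desired order.
#' @return the reordered [prior_document()].
#' @export
align_to_problem <- function(doc, problem) {
  stopifnot(inherits(doc, "prior_document"))
  vars <- if (is.character(problem)) problem else problem_variables(problem)
  sets <- lapply(doc$sets, function(s) {
    check_alignment(names(s$entries), vars, s$label)
    s$entries <- s$entries[vars]
    s
  })
  prior_document(doc$problem_name, unname(sets), doc$provenance)
}
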