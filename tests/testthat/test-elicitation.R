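test_that("the heart prompt names every variable with its unit", {
  prompt <- build_prompt(heart_disease_problem())
  for (v in c("age", "sex", "trestbps", "chol", "thalach", "oldpeak")) {
    expect_match(prompt$text, v, fixed = TRUE)
  }
  for (u in c("years", "mmHg", "mg/dl", "beats per minute", "mm")) {
    expect_match(prompt$text, u, fixed = TRUE)
  }
  expect_match(prompt$text, "logistic")
  expect_match(prompt$text, "Gaussian prior")
})

test_that("prompt construction is pure and lists each variable once", {
  p1 <- build_prompt(heart_disease_problem(), elicitation_options(provider = "x"))
  p2 <- build_prompt(heart_disease_problem(), elicitation_options(provider = "x"))
  expect_identical(p1$text, p2$text)
  expect_identical(prompt_hash(p1), prompt_hash(p2))
  expect_length(p1$sections, 5)
  expect_true(all(nzchar(unlist(p1$sections))))
  lines <- strsplit(p1$sections$data_description, "\n")[[1]]
  for (v in problem_variables(heart_disease_problem())) {
    expect_equal(sum(startsWith(lines, paste0("- ", v, ":"))), 1L)
  }
})

test_that("the prompt carries the multi-set, confidence and reflection instructions", {
  prompt <- build_prompt(heart_disease_problem(),
                         elicitation_options(n_sets = 2))
  instr <- prompt$sections$instructions
  expect_match(instr, "at least 2 sets")
  expect_match(instr, "moderately informative and weakly informative")
  expect_match(instr, "confidence score")
  expect_match(instr, "justify")
  expect_match(instr, "sources")
  expect_match(instr, "verification and reflection")
  expect_match(prompt$sections$output_format, "```json")
})

test_that("problems with inconsistent family or no variables are rejected", {
  expect_error(
    regression_problem("p",
                       list(name = "y", description = "d", kind = "binary",
                            unit = "u"),
                       family = "linear",
                       variables = data.frame(name = "x", description = "d",
                                              unit = "u")),
    "inconsistent")
  expect_error(
    regression_problem("p",
                       list(name = "y", description = "d", kind = "continuous",
                            unit = "u"),
                       family = "linear",
                       variables = data.frame(name = character(),
                                              description = character(),
                                              unit = character())),
    "at least one variable")
})

test_that("replay transports return recorded responses verbatim and deterministically", {
  dir <- withr::local_tempdir()
  prompt <- build_prompt(heart_disease_problem())
  response <- c("some reasoning", "", "```json",
                write_prior_document(heart_doc_fixture()), "```")
  record_response(dir, prompt, response, id = "t1", provenance = "unit")
  tr <- replay_transport(dir)
  r1 <- elicit(prompt, tr)
  r2 <- elicit(prompt, tr)
  expect_identical(r1$response, paste(response, collapse = "\n"))
  expect_identical(r1$response, r2$response)
  expect_identical(r1$prompt_hash, prompt_hash(prompt))
  expect_identical(r1$provenance, "unit")

  other <- build_prompt(concrete_strength_problem())
  err <- tryCatch(elicit(other, tr), error = identity)
  expect_match(conditionMessage(err), "replay miss")
  expect_match(conditionMessage(err), prompt_hash(other), fixed = TRUE)
})

test_that("bundled synthetic transcripts replay the reported sex prior and weights", {
  tr <- replay_transport(bundled_replay_dir())

  claude <- extract_prior_document(elicit(
    build_prompt(heart_disease_problem(),
                 elicitation_options(provider = "claude-opus")), tr))
  sex <- claude$sets[["Claude_Mod"]]$entries$sex$prior
  expect_equal(sex$mean, 0.7)
  expect_equal(sex$sd, 0.3)
  expect_equal(unname(vapply(claude$sets, `[[`, numeric(1), "confidence_weight")),
               c(0.65, 0.35))

  chatgpt <- extract_prior_document(elicit(
    build_prompt(heart_disease_problem(),
                 elicitation_options(provider = "chatgpt-4o-mini")), tr))
  expect_equal(chatgpt$sets[["ChatGPT_Mod"]]$entries$sex$prior$mean, 0.7)
  expect_equal(unname(vapply(chatgpt$sets, `[[`, numeric(1), "confidence_weight")),
               c(0.60, 0.40))
  # the weakly informative set is zero-centred and wide
  weak_means <- vapply(chatgpt$sets[["ChatGPT_Weak"]]$entries,
                       function(e) e$prior$mean, numeric(1))
  expect_true(all(weak_means == 0))

  concrete <- extract_prior_document(elicit(
    build_prompt(concrete_strength_problem(),
                 elicitation_options(provider = "gemini-2.5-pro")), tr))
  expect_length(concrete$sets, 2)
  expect_equal(unname(vapply(concrete$sets, `[[`, numeric(1), "confidence_weight")),
               c(0.65, 0.35))
  aligned <- align_to_problem(concrete, concrete_strength_problem())
  expect_identical(names(aligned$sets[[1]]$entries),
                   problem_variables(concrete_strength_problem()))
})

test_that("document extraction demands exactly one fenced block", {
  doc_json <- write_prior_document(heart_doc_fixture())
  one <- paste("prose", "```json", doc_json, "```", "more prose", sep = "\n")
  expect_s3_class(extract_prior_document(one), "prior_document")
  expect_error(extract_prior_document("prose only, no document"), "found 0")
  two <- paste(one, "```json", doc_json, "```", sep = "\n")
  expect_error(extract_prior_document(two), "found 2")
})

test_that("live transports surface failures instead of masking them", {
  ok <- live_transport(function(text) paste0("echo:", nchar(text)),
                       provenance = "fake-llm")
  prompt <- build_prompt(heart_disease_problem())
  rec <- elicit(prompt, ok)
  expect_identical(rec$mode, "live")
  expect_match(rec$response, "^echo:")
  bad <- live_transport(function(text) stop("socket timeout"))
  expect_error(elicit(prompt, bad), "socket timeout")
})
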