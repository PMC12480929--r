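#!/usr/bin/env Rscript
# Regenerates inst/extdata/replay/index.json. Run from the repository root
# (with the package loadable) whenever build_prompt() wording changes, since
# replay fixtures are keyed by prompt hash.

pkgload::load_all(".", quiet = TRUE)

fixtures <- list(
  list(id = "heart_claude_v1",
       file = "heart_claude_v1_synthetic.txt",
       provenance = "claude-opus (synthetic replay fixture)",
       prompt = build_prompt(heart_disease_problem(),
                             elicitation_options(provider = "claude-opus"))),
  list(id = "heart_chatgpt_v1",
       file = "heart_chatgpt_v1_synthetic.txt",
       provenance = "chatgpt-4o-mini (synthetic replay fixture)",
       prompt = build_prompt(heart_disease_problem(),
                             elicitation_options(provider = "chatgpt-4o-mini"))),
  list(id = "concrete_gemini_v1",
       file = "concrete_gemini_v1_synthetic.txt",
       provenance = "gemini-2.5-pro (synthetic replay fixture)",
       prompt = build_prompt(concrete_strength_problem(),
                             elicitation_options(provider = "gemini-2.5-pro")))
)

index <- lapply(fixtures, function(f) {
  list(id = f$id, prompt_hash = prompt_hash(f$prompt), file = f$file,
       provenance = f$provenance)
})

out <- file.path("inst", "extdata", "replay", "index.json")
writeLines(jsonlite::toJSON(index, auto_unbox = TRUE, pretty = TRUE), out)
cat("wrote", out, "\n")
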