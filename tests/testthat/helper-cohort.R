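# Default-cohort features shared by the end-to-end tests; built once per
# session (generation + extraction of 218 subjects takes ~1 min).
.accept_cache <- new.env(parent = emptyenv())

accept_data <- function() {
  if (!is.null(.accept_cache$data)) return(.accept_cache$data)
  studies <- generate_cohort(cohort_spec(seed = 1), phases = "ED")
  studies <- lapply(studies, resample_inplane, target = c(1, 1))
  ft_raw <- suppressWarnings(extract_cohort(studies, W = 25,
                                            resample_to = NULL))
  rr <- lapply(studies, function(s)
    suppressWarnings(apply_normalisation(s, "R", "roi")))
  ft_rr <- suppressWarnings(extract_cohort(rr, W = 0.05, resample_to = NULL))
  ft_combat <- harmonise_features(ft_raw)$table
  .accept_cache$data <- list(studies = studies, ft_raw = ft_raw,
                             ft_rr = ft_rr, ft_combat = ft_combat)
  .accept_cache$data
}
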