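#' Catalogue of functionally characterized defense-associated NACs
#'
#' A packaged reference table of NAC transcription factors from wheat,
#' barley, rice and *Arabidopsis* with published genetic evidence for a
#' role in pathogen defense, with their subfamily placement. Used to
#' contextualise pathogen-responsive genes against characterized
#' defense-associated family members.
#'
#' @return data.frame with `subfamily`, `species`, `gene_id`, `gene_name`,
#'   `defense_role`, `genetic_evidence`.
#' @export
characterized_defense_nacs <- function() {
  path <- system.file("extdata", "characterized_defense_nacs.tsv",
                      package = "polynac", mustWork = TRUE)
  read_tsv_plain(path)
}
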