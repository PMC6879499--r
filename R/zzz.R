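#' deepscreen: multi-dimensional network-based compound screening
#'
#' Clusters chemical compounds along three progressively deeper axes —
#' structural similarity, docking-score profiles and PPI-degree-weighted
#' network-effect profiles — each with multiscale-bootstrap AU support,
#' so divergences between the three dendrograms surface compounds with
#' similar or different system-level effects.
#'
#' @keywords internal
"_PACKAGE"
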