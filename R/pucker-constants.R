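# Frozen gamma/delta pucker classification references, derived from
# idealized rings at canonical Cremer-Pople coordinates (Q = 0.57 A;
# chairs at theta = 0/180, skew-boats on the theta = 90 equator at their
# IUPAC-named phases). Generated by data-raw/derive-pucker-references.R;
# do not edit by hand.

#' Derived pucker classification references
#'
#' Reference gamma (C1-C2-C3-C4) and delta (C1-O5-C5-C4) dihedrals in
#' degrees for the 4C1, 1C4, 2SO and 1S3 states, derived geometrically
#' (see [derive_pucker_references()]).
#' @format A data frame with columns `state`, `gamma_ref`, `delta_ref`.
#' @export
gag_pucker_refs <- data.frame(
  state = c("4C1", "1C4", "2SO", "1S3"),
  gamma_ref = c(-54.603468, 54.603468, -45.428798, -22.802542),
  delta_ref = c(59.398506, -59.398506, -50.472219, -26.858813)
)
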