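# YAML pipeline configuration: gate definitions, quality filter, clustering
# and state-classification settings in one file.

#' Read a pipeline configuration from YAML
#'
#' Recognized blocks (all optional, with the package defaults filled in):
#' \preformatted{
#' gates:
#'   C_N: {chain1: A, residues1: [68, 71, 75, 76, 79, 82],
#'         chain2: B, residues2: [82, 85, 89, 90, 93, 96], r0: 4.5}
#'   C_C: {chain1: A, residues1: [47, ..., 55],
#'         chain2: B, residues2: [61, ..., 69], r0: 4.5}
#' quality_filter: {threshold: 0.4}
#' clustering: {k: 9, max_matrix: 5000, seed: 1, scaling: none}
#' states: {margin_fraction: 0.1}
#' }
#'
#' @param path YAML file path.
#' @return List: `metrics` (list of [gating_metric()]), `quality_filter`,
#'   `clustering`, `states`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  metrics <- if (!is.null(y$gates)) {
    lapply(names(y$gates), function(nm) {
      g <- y$gates[[nm]]
      gating_metric(
        nm,
        group_spec(g$chain1 %||% "A", unlist(g$residues1)),
        group_spec(g$chain2 %||% "B", unlist(g$residues2)),
        r0 = g$r0 %||% 4.5
      )
    })
  } else {
    unname(mpc_gate_metrics("MPC1L"))
  }
  list(
    metrics = metrics,
    quality_filter = list(threshold = y$quality_filter$threshold %||% 0.4),
    clustering = list(
      k = y$clustering$k %||% 9L,
      max_matrix = y$clustering$max_matrix %||% 5000L,
      seed = y$clustering$seed %||% 1L,
      scaling = y$clustering$scaling %||% "none"
    ),
    states = list(margin_fraction = y$states$margin_fraction %||% 0.1)
  )
}
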