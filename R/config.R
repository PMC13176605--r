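## Run configuration: every tunable of the pipeline in one serializable
## object, so a run can be audited and reproduced from its resolved config.

#' Build a run configuration
#'
#' All tunables of the pipeline with their defaults. Defaults are
#' desk-scale: the published-scale random-walk budgets (steps 20000,
#' restart 0.3, iterations 10000, spread 1e6) and the 400-D embedding
#' dimension remain available by overriding the corresponding fields.
#'
#' @param L Fixed token-sequence length.
#' @param dEmb Token-embedding width.
#' @param dModel Transformer hidden size (divisible by nHead).
#' @param nLayers Transformer encoder layers.
#' @param nHead Self-attention heads.
#' @param dFf Feed-forward width.
#' @param kHeads GAT attention heads.
#' @param dPrime Per-head GAT width (output width kHeads * dPrime).
#' @param dKg Knowledge-graph vector width.
#' @param convChannels Output channels of the subgraph aggregator's
#'   convolution.
#' @param walkSteps,walkRestart,walkIterations,walkSpread Random-walk
#'   budgets (transitions per walk, restart probability, number of walks,
#'   distinct-node cap).
#' @param hopLimit Pathway-anchoring hop limit.
#' @param folds Cross-validation fold count.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement).
#' @param maxEpochs Training epoch cap.
#' @param lr,beta1,beta2 Adam settings.
#' @param dropout Dropout rate of the classifier head.
#' @param headHidden Hidden widths of the classifier head.
#' @param readout GAT readout, "mean" or "max".
#' @param usePositional Include the damped sinusoidal positional signal in
#'   the graph-branch node features (FALSE = positional-ablation mode).
#' @param useEdgeWeights Scale GAT messages by bond multiplicities.
#' @param selfLoops Add self-loops to molecular graphs.
#' @param caseSensitive Tokenizer case sensitivity.
#' @param posDamping Envelope placement in the positional encoding.
#' @param variant KG entity-family variant, "CGPDS" or "CGPD".
#' @param task "multiclass" or "binary".
#' @param split "pair" (stratified) or "drug-disjoint".
#' @param ablation Fusion variant; see \code{\link{runAblation}}.
#' @param symmetrizePairs Also train on (b, a) for every pair (a, b).
#' @param seed Master RNG seed for every randomized stage.
#' @return Object of class \code{RunConfig} (a validated named list).
#' @export
runConfig <- function(L = 128L, dEmb = 128L, dModel = 128L, nLayers = 2L,
                      nHead = 4L, dFf = 256L, kHeads = 4L, dPrime = 16L,
                      dKg = 20L, convChannels = 128L,
                      walkSteps = 200L, walkRestart = 0.3,
                      walkIterations = 100L, walkSpread = 10000L,
                      hopLimit = 4L, folds = 5L, patience = 10L,
                      maxEpochs = 200L, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, dropout = 0.3,
                      headHidden = c(256L, 128L), readout = "mean",
                      usePositional = TRUE, useEdgeWeights = TRUE,
                      selfLoops = TRUE, caseSensitive = TRUE,
                      posDamping = "multiply", variant = "CGPDS",
                      task = "multiclass", split = "pair",
                      ablation = "full", symmetrizePairs = FALSE,
                      seed = 1L) {
  cfg <- mget(names(formals()))
  intFields <- c("L", "dEmb", "dModel", "nLayers", "nHead", "dFf", "kHeads",
                 "dPrime", "dKg", "convChannels", "walkSteps",
                 "walkIterations", "walkSpread", "hopLimit", "folds",
                 "patience", "maxEpochs", "seed")
  for (f in intFields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$headHidden <- as.integer(cfg$headHidden)
  stopifnot(cfg$dModel %% cfg$nHead == 0L,
            cfg$variant %in% c("CGPDS", "CGPD"),
            cfg$task %in% c("multiclass", "binary"),
            cfg$split %in% c("pair", "drug-disjoint"),
            cfg$readout %in% c("mean", "max"),
            cfg$walkRestart >= 0, cfg$walkRestart <= 1,
            cfg$seed < 2^31)
  structure(cfg, class = "RunConfig")
}

#' Save a configuration as YAML
#' @param config A RunConfig.
#' @param path Output path.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load a configuration from YAML
#'
#' Unknown fields are rejected; missing fields fall back to defaults, so a
#' round trip through \code{\link{saveConfig}} is lossless.
#' @param path YAML file.
#' @return A RunConfig.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

## seeds derived from the master seed stay below 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
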