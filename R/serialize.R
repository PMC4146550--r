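#' Serialize a fitted hybrid classifier to JSON
#'
#' Writes every moment the model needs to be reloaded in a later session --
#' CSP filters/patterns/eigenvalues, both LDAs' means, covariances, shrinkage
#' and weights, the meta weights and scales, the decision threshold, and the
#' pipeline configuration -- so a classifier trained on previous sessions'
#' data can drive a new one.
#'
#' @param model a fitted [hybrid_bci()].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_bci"))
  cfg <- model$config
  cfg$erd_band <- unclass(cfg$erd_band)
  cfg$lrp_band <- unclass(cfg$lrp_band)
  obj <- list(
    csp = lapply(unclass(model$csp), unclass),
    lda_osc = unclass(model$lda_osc),
    lda_slow = unclass(model$lda_slow),
    meta = unclass(model$meta),
    policy = unclass(model$policy),
    cv = model$cv,
    config = unclass(cfg),
    channel_labels = model$channel_labels,
    n_trials = model$n_trials)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a serialized hybrid classifier
#'
#' @param path file written by [save_model()].
#' @return A `hybrid_bci` object numerically identical to the saved one.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$erd_band <- do.call(band, as.list(cfg$erd_band))
  cfg$lrp_band <- do.call(band, as.list(cfg$lrp_band))
  if (!is.null(cfg$gamma) && length(cfg$gamma) == 0) cfg$gamma <- NULL
  class(cfg) <- "bci_config"
  csp <- obj$csp
  class(csp) <- "bci_csp"
  fix_lda <- function(l) {
    l$sigma <- as.matrix(l$sigma)
    class(l) <- "bci_lda"
    l
  }
  meta <- obj$meta; class(meta) <- "bci_meta"
  policy <- obj$policy; class(policy) <- "bci_policy"
  structure(list(csp = csp, lda_osc = fix_lda(obj$lda_osc),
                 lda_slow = fix_lda(obj$lda_slow), meta = meta,
                 policy = policy, cv = obj$cv, config = cfg,
                 channel_labels = obj$channel_labels,
                 n_trials = obj$n_trials),
            class = "hybrid_bci")
}

#' Write a session log as CSV + JSON config snapshot
#'
#' One CSV row per trial (cue, accumulated output, decision, correctness,
#' trial clock) plus a JSON snapshot of the resolved pipeline configuration,
#' so every run is auditable.
#'
#' @param log a `bci_session`.
#' @param path output stem; writes `<path>.csv` and `<path>_config.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path) {
  stopifnot(inherits(log, "bci_session"))
  utils::write.csv(log$outcomes, paste0(path, ".csv"), row.names = FALSE)
  cfg <- log$config
  cfg$erd_band <- unclass(cfg$erd_band)
  cfg$lrp_band <- unclass(cfg$lrp_band)
  jsonlite::write_json(list(mode = log$mode, n_adapt = log$n_adapt,
                            config = unclass(cfg)),
                       paste0(path, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
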