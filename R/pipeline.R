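# End-to-end analysis: given a model, a pinned target and a phenotype,
# produce the attractor report, the MTM, ranked synergistic partners with
# control types, and optional comparator cross-checks.

#' Run the full synergistic-target identification pipeline
#'
#' Composes the package: attractor identification and basin estimation on
#' both landscapes, MTM construction, path-ensemble factorisation,
#' weighted-flipping-frequency ranking, and signal-flow control-type
#' assignment for the top candidates.  Optionally cross-checks the
#' ranking against the exhaustive systematic perturbation screen.
#'
#' @param net a [boolean_network()] or path to a .bnet file.
#' @param target given target node name.
#' @param type `"ON"` or `"OFF"` pin for the given target.
#' @param spec a [phenotype_spec()].
#' @param n_samples basin sample count (default 10000).
#' @param seed RNG seed recorded in the bundle (default 42).
#' @param top number of ranked partners to report (default 5).
#' @param ranking ranking mode for [rank_synergistic_targets()].
#' @param sps_check also run [sps_search()] and report its optimum
#'   (default FALSE; exhaustive, may be slow on large models).
#' @param output_dir optional directory: writes `attractors.json`,
#'   `targets.csv`, `mtm.graphml` and `config.json` there.
#' @return object of class `mtm_report`: `config`, `original`,
#'   `regulated` (attractor summaries), `mtm`, `scores`, `targets`
#'   (ranked data.frame with control types), and optionally `sps`.
#' @export
run_pipeline <- function(net, target, type = c("ON", "OFF"), spec,
                         n_samples = 10000L, seed = 42L, top = 5L,
                         ranking = "magnitude", sps_check = FALSE,
                         output_dir = NULL) {
  type <- match.arg(type)
  if (is.character(net)) {
    if (!file.exists(net))
      stop("model file not found: ", net, call. = FALSE)
    net <- read_bnet(net)
  }
  stopifnot(inherits(net, "boolean_network"))
  if (!(target %in% net$nodes))
    stop("target node '", target, "' not in model", call. = FALSE)
  check_markers(net, spec)
  pert <- perturbation(stats::setNames(if (type == "ON") 1L else 0L,
                                       target))
  mtm <- build_mtm(net, pert, spec, n_samples = n_samples, seed = seed)
  ens <- factorize_ensembles(mtm)
  scores <- weighted_flipping_frequency(ens)
  targets <- rank_synergistic_targets(scores, k = top, mode = ranking)
  g <- derive_signed_graph(net)
  targets$control_type <- vapply(targets$node, function(nd) {
    tryCatch(determine_control_type(g, list(target, type), nd),
             error = function(e) NA_character_)
  }, character(1))
  config <- list(target = target, type = type, n_samples = n_samples,
                 seed = seed, top = top, ranking = ranking)
  report <- structure(
    list(config = config,
         original = attractor_summary(mtm$original),
         regulated = attractor_summary(mtm$regulated),
         mtm = mtm, scores = scores, targets = targets),
    class = "mtm_report")
  if (isTRUE(sps_check)) {
    report$sps <- sps_search(net, list(target, type), spec,
                             n_samples = n_samples, seed = seed)
  }
  if (!is.null(output_dir)) write_report_bundle(report, output_dir)
  report
}

#' @export
print.mtm_report <- function(x, ...) {
  cat("MTM synergistic-target report\n")
  cat("  given target: ", x$config$target, " (", x$config$type, ")\n",
      sep = "")
  cat("  original attractors:\n")
  print(x$original)
  cat("  regulated attractors:\n")
  print(x$regulated)
  cat("  ranked synergistic partners:\n")
  print(x$targets)
  if (!is.null(x$sps)) {
    cat("  SPS optimum: ", x$sps$node[1L], " (", x$sps$type[1L],
        "), effectiveness ", sprintf("%.4f", x$sps$effectiveness[1L]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write an attractor report as JSON
#'
#' @param attractors an `attractor_set` (with basins/preferences filled).
#' @param path output file.
#' @export
write_attractor_report <- function(attractors, path) {
  stopifnot(inherits(attractors, "attractor_set"))
  payload <- lapply(attractors, function(a) list(
    id = a$id, kind = a$kind, states = a$states,
    basin_fraction = a$basin_fraction, preference = a$preference))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_report_bundle <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_attractor_report(report$mtm$original,
                         file.path(output_dir, "attractors_original.json"))
  write_attractor_report(report$mtm$regulated,
                         file.path(output_dir, "attractors_regulated.json"))
  utils::write.csv(report$targets,
                   file.path(output_dir, "targets.csv"),
                   row.names = FALSE, quote = FALSE)
  export_mtm_graphml(report$mtm, file.path(output_dir, "mtm.graphml"))
  jsonlite::write_json(report$config,
                       file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
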