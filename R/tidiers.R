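# broom-style tidiers for the package's result objects.

#' Tidy an audit report
#'
#' @param x An [run_audit()] result.
#' @param ... Unused.
#' @return The per-element summary tibble: one row per (model, element) with
#'   `n`, `mae`, `rmse`.
#' @export
tidy.audit_report <- function(x, ...) {
  dplyr::rename(x$per_element, element = "label")
}

#' One-row-per-model overview of an audit report
#'
#' @param x An [run_audit()] result.
#' @param ... Unused.
#' @return A tibble with one row per model: overall force and energy MAE and
#'   RMSE, outlier count, cluster count and problem size.
#' @export
glance.audit_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    f <- x$summary[x$summary$model == m & x$summary$quantity == "force", ]
    e <- x$summary[x$summary$model == m & x$summary$quantity == "energy", ]
    tibble(
      model = m,
      force_mae = f$mae, force_rmse = f$rmse,
      energy_mae = e$mae, energy_rmse = e$rmse,
      n_frames = x$n_frames, n_atoms = x$n_atoms,
      n_clusters = x$assignment$n_total,
      n_outliers = sum(x$outliers$model == m)
    )
  }))
}

#' Tidy a cluster assignment
#'
#' @param x A [cluster_configurations()] result.
#' @param ... Unused.
#' @return A tibble with one row per frame: `frame`, `structural_label`,
#'   `cluster_label`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(
    frame = seq_along(x$labels),
    structural_label = x$structural_labels,
    cluster_label = x$labels
  )
}

#' One-row summary of a cluster assignment
#'
#' @param x A [cluster_configurations()] result.
#' @param ... Unused.
#' @return A tibble with cluster counts and, when summaries are attached, the
#'   spread (max/min) of per-cluster force MAEs.
#' @export
glance.cluster_assignment <- function(x, ...) {
  out <- tibble(
    n_frames = length(x$labels),
    n_structural = x$n_structural,
    n_clusters = x$n_total
  )
  if (!is.null(x$summaries)) {
    out$force_mae_spread <- max(x$summaries$force_mae) / min(x$summaries$force_mae)
  }
  out
}

#' Tidy an error table
#'
#' @param x An [compute_error_table()] result.
#' @param ... Unused.
#' @return The long per-element sample tibble of [per_element_errors()].
#' @export
tidy.error_table <- function(x, ...) {
  per_element_errors(x)
}

#' One-row summary of an error table
#'
#' @param x An [compute_error_table()] result.
#' @param ... Unused.
#' @return A tibble with overall force MAE/RMSE and energy MAE/RMSE.
#' @export
glance.error_table <- function(x, ...) {
  f <- error_summary(x)
  e <- energy_summary(x)
  tibble(
    force_mae = f$mae, force_rmse = f$rmse,
    energy_mae = e$mae, energy_rmse = e$rmse,
    n_frames = nrow(x$atom_errors), n_atoms = ncol(x$atom_errors),
    convention = x$convention, source_mode = x$source_mode
  )
}
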