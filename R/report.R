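config_error <- function(...) {
  stop(structure(
    class = c("ffaudit_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Audit configuration
#'
#' Collects every knob of a full audit run. All numbers in the resulting
#' report are regenerable from the inputs plus this configuration (the seed
#' fixes the clustering stage).
#'
#' @param dataset A [configuration_set()] or a path to one (`.xyz`/`.npz`).
#' @param predictions A [prediction_record()], a path, or a (named) list of
#'   either; each prediction stream is audited against `dataset`.
#' @param out_dir Output directory (created if missing).
#' @param train_subset Optional training-subset frames for the
#'   representativeness comparison: a [make_subset()] view, an integer
#'   vector, or a path to a text file of 1-based frame indices.
#' @param convention Force-error convention for the tables
#'   (see [compute_error_table()]).
#' @param window Timeline smoothing window (frames).
#' @param n_total,n_structural Cluster counts (see [cluster_configurations()]).
#' @param kde_bandwidth `NULL`/`"scott"` for Scott's rule or a positive number.
#' @param outlier_k Robust outlier threshold (see [correlation_scatter()]).
#' @param seed Integer seed for all stochastic stages.
#' @param write_plots Write static figure files (failures degrade to CSV-only
#'   with a warning).
#' @return An object of class `audit_config`.
#' @export
audit_config <- function(dataset, predictions, out_dir,
                         train_subset = NULL,
                         convention = c("component_mae", "vector_norm"),
                         window = 25L, n_total = 40L, n_structural = 10L,
                         kde_bandwidth = NULL, outlier_k = 4, seed = 1L,
                         write_plots = TRUE) {
  convention <- match.arg(convention)
  if (missing(dataset) || is.null(dataset)) config_error("an input dataset is required")
  if (missing(predictions) || is.null(predictions) || length(predictions) == 0) {
    config_error("at least one prediction stream is required")
  }
  if (!inherits(predictions, "prediction_record") && !is.character(predictions) &&
    !is.list(predictions)) {
    config_error("predictions must be a prediction_record, a path, or a list of either")
  }
  if (is.character(kde_bandwidth)) {
    if (!identical(kde_bandwidth, "scott")) {
      config_error("kde_bandwidth must be 'scott' or a positive number")
    }
    kde_bandwidth <- NULL
  }
  structure(
    list(
      dataset = dataset, predictions = predictions, out_dir = out_dir,
      train_subset = train_subset, convention = convention,
      window = as.integer(window), n_total = as.integer(n_total),
      n_structural = as.integer(n_structural), kde_bandwidth = kde_bandwidth,
      outlier_k = outlier_k, seed = as.integer(seed), write_plots = write_plots
    ),
    class = "audit_config"
  )
}

read_dataset_file <- function(path) {
  if (!is.character(path)) {
    return(path)
  }
  if (!file.exists(path)) config_error("dataset file not found: ", path)
  if (grepl("\\.npz$", path, ignore.case = TRUE)) read_npz_bundle(path) else read_extxyz(path)
}

#' Run a full force-field audit
#'
#' Orchestrates the whole pipeline over one dataset and one or more
#' prediction streams: error tables, overall and per-element summaries,
#' kernel-density error curves, smoothed error timelines, shared two-stage
#' clustering with ascending per-cluster error profiles, predicted-vs-true
#' scatter with robust outlier flags, a radius-of-gyration series,
#' training-set representativeness (when a training subset is supplied) and
#' per-atom error-annotated structures. All tables are written as CSV, plots
#' as PNG (degrading to CSV-only with a warning on plotting failure) and an
#' overall JSON report with a file manifest. When several models are audited
#' together they share one clustering, so their cluster profiles are
#' directly comparable. Any stage failure aborts with a stage-named error
#' and removes partial outputs.
#'
#' @param config An [audit_config()].
#' @return An object of class `audit_report` (invisible file side effects in
#'   `config$out_dir`).
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(file.path(config$out_dir, written))
      stop("audit stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("load", {
    d <- read_dataset_file(config$dataset)
    if (is.null(d$energies) || is.null(d$forces)) {
      stop("dataset must carry reference energies and forces")
    }
    d
  })

  preds <- stage("predictions", {
    p <- config$predictions
    if (inherits(p, "prediction_record") || is.character(p)) p <- list(p)
    p <- lapply(p, function(x) {
      if (is.character(x)) load_prestored_predictions(x, ds) else x
    })
    nms <- names(p) %||% rep("", length(p))
    auto <- vapply(p, function(x) x$source_id, character(1))
    names(p) <- ifelse(nzchar(nms), nms, make.unique(auto))
    for (x in p) check_aligned(ds, x)
    p
  })
  models <- names(preds)

  tables <- stage("error_table", {
    lapply(preds, function(p) compute_error_table(ds, p, convention = config$convention))
  })
  norm_tables <- lapply(preds, function(p) {
    compute_error_table(ds, p, convention = "vector_norm")
  })

  summary_tbl <- stage("summary", {
    dplyr::bind_rows(lapply(models, function(m) {
      dplyr::bind_rows(
        dplyr::mutate(error_summary(tables[[m]]), model = m, quantity = "force"),
        dplyr::mutate(energy_summary(tables[[m]]), model = m, quantity = "energy")
      )
    }))
  })
  emit("summary.csv", function(p) write.csv(summary_tbl, p, row.names = FALSE))

  per_element_tbl <- stage("per_element", {
    dplyr::bind_rows(lapply(models, function(m) {
      dplyr::mutate(element_summary(tables[[m]]), model = m, .before = 1)
    }))
  })
  emit("per_element.csv", function(p) write.csv(per_element_tbl, p, row.names = FALSE))

  densities <- stage("kde", {
    dplyr::bind_rows(lapply(models, function(m) {
      samples <- per_element_errors(tables[[m]])
      curves <- lapply(split(samples$error, samples$element), function(x) {
        tryCatch(kde_curve(x, bandwidth = config$kde_bandwidth),
          error = function(e) NULL
        )
      })
      eng <- tryCatch(
        kde_curve(abs(tables[[m]]$energy_errors), bandwidth = config$kde_bandwidth),
        error = function(e) NULL
      )
      curves <- c(curves, list(energy = eng))
      dplyr::bind_rows(lapply(names(curves), function(nm) {
        if (is.null(curves[[nm]])) {
          return(NULL)
        }
        tibble(
          model = m, series = nm, grid = curves[[nm]]$grid,
          density = curves[[nm]]$density
        )
      }))
    }))
  })
  emit("densities.csv", function(p) write.csv(densities, p, row.names = FALSE))

  timelines <- stage("timeline", {
    dplyr::bind_rows(lapply(models, function(m) {
      fm <- rowMeans(tables[[m]]$atom_errors)
      ea <- abs(tables[[m]]$energy_errors)
      tibble(
        model = m, frame = seq_along(fm),
        force_mae = fm, energy_abs = ea,
        force_mae_smooth = smooth_timeline(fm, config$window),
        energy_abs_smooth = smooth_timeline(ea, config$window)
      )
    }))
  })
  emit("timeline.csv", function(p) write.csv(timelines, p, row.names = FALSE))

  assignment <- stage("clustering", {
    cluster_configurations(ds,
      n_total = config$n_total,
      n_structural = config$n_structural, seed = config$seed
    )
  })
  emit("assignment.csv", function(p) {
    write.csv(tibble(
      frame = seq_along(assignment$labels),
      structural_label = assignment$structural_labels,
      cluster_label = assignment$labels
    ), p, row.names = FALSE)
  })
  profiles <- stage("cluster_profile", {
    dplyr::bind_rows(lapply(models, function(m) {
      a <- summarize_clusters(assignment, tables[[m]])
      prof <- cluster_error_profile(a, "force_mae")
      prof$rank <- seq_len(nrow(prof))
      prof$energy_mae <- a$summaries$energy_mae[match(prof$cluster, a$summaries$cluster)]
      dplyr::mutate(prof, model = m, .before = 1)
    }))
  })
  emit("cluster_profile.csv", function(p) write.csv(profiles, p, row.names = FALSE))

  outliers <- stage("scatter", {
    dplyr::bind_rows(lapply(models, function(m) {
      dplyr::bind_rows(
        dplyr::mutate(
          dplyr::filter(
            correlation_scatter(ds, preds[[m]], "energy", k = config$outlier_k),
            .data$outlier
          ),
          model = m, quantity = "energy", .before = 1
        ),
        dplyr::mutate(
          dplyr::filter(
            correlation_scatter(ds, preds[[m]], "force_component", k = config$outlier_k),
            .data$outlier
          ),
          model = m, quantity = "force_component", .before = 1
        )
      )
    }))
  })
  emit("outliers.csv", function(p) write.csv(outliers, p, row.names = FALSE))

  gyr <- stage("gyradius", radius_of_gyration(ds))
  emit("gyradius.csv", function(p) write.csv(gyr, p, row.names = FALSE))

  representativeness <- NULL
  if (!is.null(config$train_subset)) {
    representativeness <- stage("representativeness", {
      idx <- config$train_subset
      if (is.character(idx)) idx <- as.integer(readLines(idx))
      if (inherits(idx, "subset_view")) idx <- idx$frame_indices
      sub <- make_subset(ds, idx, "train")$frame_indices
      dplyr::bind_rows(
        dplyr::mutate(
          compare_distributions(as.vector(ds$forces), as.vector(ds$forces[sub, , , drop = FALSE])),
          quantity = "force", .before = 1
        ),
        dplyr::mutate(
          compare_distributions(ds$energies, ds$energies[sub]),
          quantity = "energy", .before = 1
        ),
        dplyr::mutate(
          compare_distributions(gyr$value, gyr$value[sub]),
          quantity = "gyradius", .before = 1
        )
      )
    })
    emit("representativeness.csv", function(p) {
      write.csv(representativeness, p, row.names = FALSE)
    })
  }

  stage("annotate", {
    for (m in models) {
      emit(paste0("annotated_", gsub("[^A-Za-z0-9_.-]", "_", m), ".extxyz"), function(p) {
        export_annotated_structure(ds, norm_tables[[m]], frames = "mean", path = p)
      })
    }
  })

  if (isTRUE(config$write_plots)) {
    plot_specs <- list(
      densities = function() plot_error_densities(densities),
      timeline = function() plot_timeline(timelines),
      clusters = function() plot_cluster_profile(profiles),
      gyradius = function() plot_gyradius(gyr, timelines)
    )
    for (nm in names(plot_specs)) {
      ok <- tryCatch(
        {
          pl <- plot_specs[[nm]]()
          emit(paste0(nm, ".png"), function(p) {
            ggplot2::ggsave(p, pl, width = 7, height = 4.5, dpi = 120)
          })
          TRUE
        },
        error = function(e) {
          warning("plot '", nm, "' failed (", conditionMessage(e),
            "); continuing with CSV output only",
            call. = FALSE
          )
          FALSE
        }
      )
    }
  }

  overall <- lapply(models, function(m) {
    f <- summary_tbl[summary_tbl$model == m & summary_tbl$quantity == "force", ]
    e <- summary_tbl[summary_tbl$model == m & summary_tbl$quantity == "energy", ]
    list(
      force = list(mae = f$mae, rmse = f$rmse, n = f$n),
      energy = list(mae = e$mae, rmse = e$rmse, n = e$n),
      n_outliers = sum(outliers$model == m)
    )
  })
  names(overall) <- models

  report_json <- list(
    schema_version = 1L,
    dataset = list(name = ds$name, n_frames = n_frames(ds), n_atoms = n_atoms(ds)),
    convention = config$convention,
    seed = config$seed,
    n_clusters = assignment$n_total,
    models = overall,
    manifest = as.list(sort(c(written, "report.json")))
  )
  emit("report.json", function(p) {
    jsonlite::write_json(report_json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  structure(
    list(
      config = config, dataset_name = ds$name, n_frames = n_frames(ds),
      n_atoms = n_atoms(ds), models = models, summary = summary_tbl,
      per_element = per_element_tbl, densities = densities,
      timelines = timelines, assignment = assignment, profiles = profiles,
      outliers = outliers, gyradius = gyr,
      representativeness = representativeness,
      manifest = sort(unique(c(written, "report.json"))), out_dir = config$out_dir
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report> '", x$dataset_name, "': ", x$n_frames, " frames x ",
    x$n_atoms, " atoms; models: ", paste(x$models, collapse = ", "), "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Export a per-atom error-annotated structure
#'
#' Writes one structure whose atoms carry their mean force error over the
#' selected frames, for colouring in external viewers: either extended XYZ
#' with an extra `atom_error` per-atom column, or PDB with the error in the
#' B-factor field (clamped to the field's width). Per-atom projections are
#' conventionally based on force-error vector norms; pass a `vector_norm`
#' error table for that convention.
#'
#' @param ds The [configuration_set()] (the first selected frame provides the
#'   coordinates).
#' @param table An aligned [compute_error_table()] result.
#' @param frames `"mean"` (average over all frames) or a [make_subset()] view.
#' @param path Output file.
#' @param format `"extxyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
export_annotated_structure <- function(ds, table, frames = "mean", path,
                                       format = c("extxyz", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "configuration_set"), inherits(table, "error_table"))
  if (nrow(table$atom_errors) != n_frames(ds) || ncol(table$atom_errors) != n_atoms(ds)) {
    stop("error table is not aligned with the dataset", call. = FALSE)
  }
  fi <- if (identical(frames, "mean")) {
    seq_len(n_frames(ds))
  } else if (inherits(frames, "subset_view")) {
    frames$frame_indices
  } else {
    as.integer(frames)
  }
  if (length(fi) == 0) stop("empty frame selection", call. = FALSE)
  ann <- colMeans(table$atom_errors[fi, , drop = FALSE])
  geom <- matrix(ds$positions[fi[1], , ], ncol = 3L)
  if (format == "extxyz") {
    one <- configuration_set(ds$symbols, geom,
      name = ds$name,
      extra_atom_props = list(atom_error = matrix(ann, nrow = 1L))
    )
    write_extxyz(one, path)
  } else {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("PDB export requires the bio3d package", call. = FALSE)
    }
    na <- n_atoms(ds)
    bio3d::write.pdb(
      file = path, xyz = as.vector(t(geom)),
      resno = rep(1L, na), resid = rep("MOL", na), eleno = seq_len(na),
      elety = ds$symbols, chain = rep("A", na), o = rep(1, na),
      b = pmin(pmax(ann, 0), 999.99)
    )
  }
  invisible(path)
}
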