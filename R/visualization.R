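# Declarative figure building from the visualization table (or an
# auto-generated default), plus simple base-graphics rendering.  The
# testable artifact is the figure-data structure; rendering is a thin layer
# over it.

#' Auto-generate a default visualization table
#'
#' One time-course plot per observable, grouped by simulation condition,
#' linear axes.
#'
#' @param problem A `petab_problem`.
#' @return A canonical visualization table (zero rows when there are no
#'   measurements).
#' @export
default_visualization <- function(problem) {
  obs_ids <- unique(problem$measurements$observableId)
  df <- .df(plotId = paste0("plot_", obs_ids, recycle0 = TRUE),
            plotType = rep("time_course", length(obs_ids)),
            yObservables = obs_ids)
  .canonicalize_table(df, "visualization")
}

#' Build declarative figure data from measurements and simulations
#'
#' For each plot of the visualization table (or the default one), groups
#' the measurements of its observables, aggregates replicate values at the
#' same x (mean, and sample SD where at least two replicates share an x),
#' and pairs each measured series with a simulated one when a simulation
#' table is supplied.  Time-course plots use time as x; dose-response plots
#' use the named condition-table column, one x value per simulation
#' condition.
#'
#' @param problem A `petab_problem`.
#' @param simulations Optional simulation table from [simulate_problem()].
#' @return A list of `petab_figure` objects: each has `plot_id`,
#'   `plot_type`, `x_label`, `x_scale`, `y_scale` and `series` (each series:
#'   `label`, `source` (`"measurement"`/`"simulation"`), sorted `x`, `y`,
#'   `spread`).
#' @export
build_figure_data <- function(problem, simulations = NULL) {
  vis <- problem$visualization
  if (is.null(vis) || nrow(vis) == 0L) vis <- default_visualization(problem)
  m <- problem$measurements
  sim_values <- if (!is.null(simulations)) {
    as.numeric(simulations$simulation)
  } else NULL

  x_of <- function(rows, plot) {
    if (plot$plotType == "time_course") return(m$time[rows])
    target <- plot$xVariable
    if (!target %in% names(problem$conditions)) {
      petab_error("missing_x_variable",
                  sprintf("plot '%s': condition table has no column '%s'",
                          plot$plotId, target),
                  target = target)
    }
    vals <- vapply(m$simulationConditionId[rows], function(cid) {
      cell <- problem$conditions[[target]][
        problem$conditions$conditionId == cid]
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) {
        v <- problem$parameters$nominalValue[
          problem$parameters$parameterId == cell]
      }
      if (length(v) == 0L) NA_real_ else v
    }, numeric(1))
    vals
  }

  group_rows <- function(rows, grouping) {
    key <- switch(grouping,
      by_dataset_id = if ("datasetId" %in% names(m)) m$datasetId[rows]
                      else m$simulationConditionId[rows],
      by_simulation_condition = m$simulationConditionId[rows],
      by_observable = m$observableId[rows])
    key[is.na(key)] <- "<none>"
    split(rows, key)
  }

  aggregate_series <- function(rows, x, values, y_offset, x_offset) {
    ok <- !is.na(x) & !is.na(values)
    x <- x[ok]; values <- values[ok]
    xs <- sort(unique(x))
    y <- vapply(xs, function(v) mean(values[x == v]), numeric(1))
    spread <- vapply(xs, function(v) {
      vv <- values[x == v]
      if (length(vv) >= 2L) stats::sd(vv) else NA_real_
    }, numeric(1))
    list(x = xs + x_offset, y = y + y_offset, spread = spread)
  }

  figures <- list()
  for (pid in unique(vis$plotId)) {
    prow <- vis[vis$plotId == pid, , drop = FALSE][1, ]
    if (!prow$plotType %in% .plot_types) next  # linted as VIS_PLOT_TYPE
    y_obs <- vapply(parse_override_list(prow$yObservables), as.character,
                    character(1))
    series <- list()
    for (oid in y_obs) {
      rows <- which(m$observableId == oid)
      if (length(rows) == 0L) next
      for (grp in names(groups <- group_rows(rows, prow$grouping))) {
        grows <- groups[[grp]]
        x <- x_of(grows, prow)
        label <- if (length(groups) > 1L || grp != "<none>") {
          paste0(oid, " (", grp, ")")
        } else oid
        ms <- aggregate_series(grows, x, m$measurement[grows],
                               prow$yOffset, prow$xOffset)
        series[[length(series) + 1L]] <-
          c(list(label = label, source = "measurement"), ms)
        if (!is.null(sim_values)) {
          ss <- aggregate_series(grows, x, sim_values[grows],
                                 prow$yOffset, prow$xOffset)
          series[[length(series) + 1L]] <-
            c(list(label = paste(label, "simulation"),
                   source = "simulation"), ss)
        }
      }
    }
    figures[[length(figures) + 1L]] <- structure(
      list(plot_id = pid, plot_type = prow$plotType,
           x_label = if (prow$plotType == "time_course") "time"
                     else prow$xVariable,
           x_scale = prow$xScale, y_scale = prow$yScale, series = series),
      class = "petab_figure")
  }
  figures
}

#' Render figure data to image files
#'
#' One PNG per figure: measurement series as points (with error bars where
#' replicate spread exists), simulation series as lines.
#'
#' @param figures List of `petab_figure` objects from [build_figure_data()].
#' @param directory Output directory.
#' @param width,height Device size in pixels.
#' @return Character vector of the written file paths.
#' @export
render_figures <- function(figures, directory, width = 800, height = 600) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (fig in figures) {
    path <- file.path(directory, paste0(fig$plot_id, ".png"))
    grDevices::png(path, width = width, height = height)
    tryCatch({
      xs <- unlist(lapply(fig$series, `[[`, "x"))
      ys <- unlist(lapply(fig$series, `[[`, "y"))
      if (length(xs) == 0L) {
        graphics::plot.new()
        graphics::title(main = fig$plot_id)
      } else {
        log_axes <- paste0(if (fig$x_scale == "log10") "x" else "",
                           if (fig$y_scale == "log10") "y" else "")
        graphics::plot(range(xs), range(ys, na.rm = TRUE), type = "n",
                       xlab = fig$x_label, ylab = "value",
                       main = fig$plot_id, log = log_axes)
        for (i in seq_along(fig$series)) {
          s <- fig$series[[i]]
          col <- (i + 1L) %/% 2L
          if (s$source == "measurement") {
            graphics::points(s$x, s$y, pch = 19, col = col)
            has_spread <- !is.na(s$spread)
            if (any(has_spread)) {
              graphics::arrows(s$x[has_spread],
                               s$y[has_spread] - s$spread[has_spread],
                               s$x[has_spread],
                               s$y[has_spread] + s$spread[has_spread],
                               angle = 90, code = 3, length = 0.04,
                               col = col)
            }
          } else {
            graphics::lines(s$x, s$y, col = col, lwd = 2)
          }
        }
        graphics::legend("topright",
                         legend = vapply(fig$series, `[[`, character(1),
                                         "label"),
                         col = (seq_along(fig$series) + 1L) %/% 2L,
                         pch = ifelse(vapply(fig$series, `[[`, character(1),
                                             "source") == "measurement",
                                      19, NA),
                         lty = ifelse(vapply(fig$series, `[[`, character(1),
                                             "source") == "simulation",
                                      1, NA),
                         cex = 0.8)
      }
    }, finally = grDevices::dev.off())
    paths <- c(paths, path)
  }
  paths
}
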