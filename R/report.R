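#' Write a static longitudinal report for a cohort
#'
#' Produces the CSV tables (labels, per-channel trajectories, per-array-type
#' category population tables, group-wise 1 kHz aggregates) and, optionally,
#' summary figures (population stacked bars and group mean +/- SEM 1 kHz
#' curves) for a classified cohort.
#'
#' @param cohort An [eis_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param labels Optional label table; defaults to [classify_cohort()] output.
#' @param plots If `TRUE`, also write PNG figures.
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(cohort, out_dir, labels = NULL, plots = FALSE) {
  stopifnot(inherits(cohort, "eis_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(labels)) labels <- classify_cohort(cohort)
  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(labels, "labels.csv")
  traj <- channel_trajectories(cohort, labels)
  put(traj, "trajectories.csv")

  idx <- cohort_index(cohort)
  sessions <- unique(idx$session)
  sessions <- sessions[order(session_rank(sessions))]
  for (typ in unique(idx$array_type)) {
    sub <- idx[idx$array_type == typ, ]
    roster <- unique(sub[c("array_id", "channel")])
    keys <- label_keys(labels) %in% label_keys(sub)
    pop <- population_table(labels[keys, , drop = FALSE], roster, sessions)
    put(data.frame(session = rownames(pop), pop, check.names = FALSE),
        sprintf("population_%s.csv", tolower(typ)))
  }

  agg_in <- data.frame(category = traj$category, session = traj$session,
                       value = log10(traj$z1k_ohm))
  agg_in <- agg_in[!is.na(agg_in$value) & !is.na(agg_in$category), ]
  agg <- aggregate_metric(agg_in)
  names(agg)[names(agg) %in% c("mean", "sem")] <-
    c("mean_log10_z1k", "sem_log10_z1k")
  put(agg, "aggregates_z1k.csv")

  if (plots) {
    for (typ in unique(idx$array_type)) {
      path <- file.path(out_dir, sprintf("population_%s.png", tolower(typ)))
      pop <- read.csv(file.path(out_dir,
                                sprintf("population_%s.csv", tolower(typ))),
                      check.names = FALSE)
      grDevices::png(path, width = 900, height = 500)
      m <- t(as.matrix(pop[, -1]))
      graphics::barplot(m, names.arg = pop$session, las = 2,
                        col = grDevices::hcl.colors(nrow(m), "Set 2"),
                        main = sprintf("Category populations (%s)", typ),
                        ylab = "channels")
      graphics::legend("topright", legend = rownames(m), cex = 0.8,
                       fill = grDevices::hcl.colors(nrow(m), "Set 2"))
      grDevices::dev.off()
      files <- c(files, path)
    }
    path <- file.path(out_dir, "z1k_by_group.png")
    grDevices::png(path, width = 900, height = 500)
    ok <- !is.na(agg$mean_log10_z1k)
    graphics::plot(NA, xlim = range(session_rank(agg$session)),
                   ylim = range(agg$mean_log10_z1k[ok]) + c(-0.3, 0.3),
                   xlab = "session (weeks; -1 = in vitro, 0 = 1 h)",
                   ylab = "log10 |Z| at 1 kHz (ohm)",
                   main = "1 kHz impedance by category")
    cats <- unique(agg$category[ok])
    for (i in seq_along(cats)) {
      d <- agg[agg$category == cats[i] & ok, ]
      xx <- session_rank(d$session)
      graphics::lines(xx, d$mean_log10_z1k, col = i, type = "b", pch = 16)
      graphics::arrows(xx, d$mean_log10_z1k - d$sem_log10_z1k, xx,
                       d$mean_log10_z1k + d$sem_log10_z1k, angle = 90,
                       code = 3, length = 0.03, col = i)
    }
    graphics::legend("topright", legend = cats, col = seq_along(cats),
                     lty = 1, pch = 16, cex = 0.8)
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}
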