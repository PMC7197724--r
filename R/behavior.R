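# Larval motility analysis: tracking-export parsing, protocol segmentation,
# per-animal motility metrics, and two-group statistics including the PTZ
# fold-change response.

TRACKING_COLUMNS <- c("animal_id", "group", "bin_start_s", "bin_end_s",
                      "lighting", "smldist", "lardist", "smldur", "lardur")

#' Define the lighting protocol
#'
#' Ordered lighting phases with durations that are whole multiples of the
#' tracker's integration period. Default: 15 minutes as dark/light/dark,
#' 5 minutes each, integrated over 300 s bins.
#'
#' @param lighting character vector of `"dark"`/`"light"` phase labels.
#' @param duration_s phase durations in seconds.
#' @param integration_s tracker integration period in seconds.
#' @return a `protocol_spec` object.
#' @export
protocol_spec <- function(lighting = c("dark", "light", "dark"),
                          duration_s = c(300, 300, 300),
                          integration_s = 300) {
  stopifnot(length(lighting) == length(duration_s), length(lighting) >= 1)
  if (!all(lighting %in% c("dark", "light")))
    stop("lighting must be \"dark\" or \"light\"")
  if (any(duration_s <= 0) || any(duration_s %% integration_s != 0))
    stop("phase durations must be positive multiples of integration_s")
  structure(list(phases = data.frame(lighting = lighting,
                                     duration_s = duration_s,
                                     stringsAsFactors = FALSE),
                 integration_s = integration_s),
            class = "protocol_spec")
}

#' Read a per-well tracking export
#'
#' Parses a CSV of per-animal, per-integration-bin movement quantities
#' (distances in mm, durations in seconds; columns `TRACKING_COLUMNS`, plus
#' any extras such as `replicate`, which are preserved). Header comment
#' lines starting with `#` are ignored. Rows violating the bin invariants
#' (negative quantities, non-increasing bin bounds, movement duration
#' exceeding the bin length) are rejected with reasons, attached as
#' attribute `rejected`.
#'
#' @param path CSV path.
#' @return data frame of validated bins.
#' @export
read_tracking_export <- function(path) {
  bins <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACKING_COLUMNS, names(bins))
  if (length(missing_cols))
    stop("tracking export is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(bins) == 0L) {
    attr(bins, "rejected") <- data.frame(row = integer(), reason = character())
    return(bins)
  }
  reasons <- rep(NA_character_, nrow(bins))
  neg <- bins$smldist < 0 | bins$lardist < 0 | bins$smldur < 0 | bins$lardur < 0
  reasons[neg] <- "negative movement quantity"
  bad_bounds <- bins$bin_end_s <= bins$bin_start_s
  reasons[bad_bounds & is.na(reasons)] <- "bin_end_s <= bin_start_s"
  too_long <- (bins$smldur + bins$lardur) >
    (bins$bin_end_s - bins$bin_start_s) + 1e-9
  reasons[too_long & is.na(reasons)] <- "movement duration exceeds bin length"
  rejected <- data.frame(row = which(!is.na(reasons)),
                         reason = reasons[!is.na(reasons)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) message(nrow(rejected), " tracking row(s) rejected")
  out <- bins[is.na(reasons), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Assign protocol phases to bins
#'
#' Labels every bin with its phase index and protocol lighting. Phase
#' windows are half-open `[start, end)`; a bin must fall entirely inside one
#' phase — a straddling bin indicates a malformed export and is an error.
#'
#' @param bins tracking bins (see [read_tracking_export()]).
#' @param protocol a [protocol_spec()].
#' @return `bins` with added `phase` (integer) and `phase_lighting` columns.
#' @export
split_phases <- function(bins, protocol = protocol_spec()) {
  bounds <- cumsum(c(0, protocol$phases$duration_s))
  n_phase <- nrow(protocol$phases)
  phase <- rep(NA_integer_, nrow(bins))
  for (p in seq_len(n_phase)) {
    inside <- bins$bin_start_s >= bounds[p] & bins$bin_end_s <= bounds[p + 1]
    phase[inside & is.na(phase)] <- p
  }
  if (anyNA(phase)) {
    bad <- which(is.na(phase))[1]
    stop(sprintf("bin [%g, %g) straddles a phase boundary or lies outside the protocol",
                 bins$bin_start_s[bad], bins$bin_end_s[bad]))
  }
  bins$phase <- phase
  bins$phase_lighting <- protocol$phases$lighting[phase]
  bins
}

#' Per-animal motility summaries
#'
#' For each animal: total distance = sum of `smldist + lardist` over all
#' bins, and swim speed = total distance / total movement duration
#' (`smldur + lardur`) — a ratio of sums, not a mean of per-bin speeds.
#' Per-phase versions of both are appended as `distance_phase<k>` /
#' `speed_phase<k>`. An animal with zero total movement duration keeps its
#' distance but has an undefined (NA) speed, flagged via `speed_defined`.
#'
#' @param bins tracking bins for one or more animals.
#' @param protocol a [protocol_spec()].
#' @return data frame with one row per animal: `animal_id`, `group`,
#'   (`replicate` if present in `bins`), `total_distance_mm`,
#'   `swim_speed_mm_per_s`, `speed_defined`, and the per-phase columns.
#' @export
summarize_larvae <- function(bins, protocol = protocol_spec()) {
  bins <- split_phases(bins, protocol)
  bins$dist <- bins$smldist + bins$lardist
  bins$dur <- bins$smldur + bins$lardur
  ids <- unique(bins$animal_id)
  n_phase <- nrow(protocol$phases)
  has_rep <- "replicate" %in% names(bins)
  rows <- lapply(ids, function(id) {
    b <- bins[bins$animal_id == id, , drop = FALSE]
    dist <- sum(b$dist)
    dur <- sum(b$dur)
    row <- data.frame(animal_id = id, group = b$group[1],
                      stringsAsFactors = FALSE)
    if (has_rep) row$replicate <- b$replicate[1]
    row$total_distance_mm <- dist
    row$swim_speed_mm_per_s <- if (dur > 0) dist / dur else NA_real_
    row$speed_defined <- dur > 0
    for (p in seq_len(n_phase)) {
      bp <- b[b$phase == p, , drop = FALSE]
      dp <- sum(bp$dist)
      tp <- sum(bp$dur)
      row[[paste0("distance_phase", p)]] <- dp
      row[[paste0("speed_phase", p)]] <- if (tp > 0) dp / tp else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

group_values <- function(summaries, metric, group, level, na_metric_note) {
  s <- summaries[summaries$group == group, , drop = FALSE]
  if (level == "replicate") {
    if (!"replicate" %in% names(s))
      stop("level = \"replicate\" requires a replicate column in summaries")
    v <- s[[metric]]
    keep <- !is.na(v)
    if (sum(!keep)) message(sum(!keep), " ", na_metric_note, " in group ",
                            group, " excluded")
    tapply(v[keep], s$replicate[keep], mean)
  } else {
    v <- s[[metric]]
    if (sum(is.na(v))) message(sum(is.na(v)), " ", na_metric_note,
                               " in group ", group, " excluded")
    v[!is.na(v)]
  }
}

#' Two-group comparison of a motility metric
#'
#' Two-tailed two-sample t-test of `metric` between groups, with per-group
#' means, standard errors of the mean, and the fold change
#' `mean_b / mean_a`. Analysis level is either per-animal (each animal one
#' observation) or per-replicate (replicate means are the observations,
#' matching error bars computed over independent experiments). Animals with
#' an undefined metric (e.g. speed with zero movement) are excluded with a
#' logged count.
#'
#' When both groups have zero variance the test statistic is degenerate:
#' equal means give t = 0, p = 1; unequal means give |t| = Inf, p = 0, and
#' `degenerate = TRUE`.
#'
#' @param summaries data frame from [summarize_larvae()] (or any per-animal
#'   table with `group` and the metric column).
#' @param metric metric column name, e.g. `"total_distance_mm"`.
#' @param group_a,group_b group labels (a is the reference for the fold
#'   change).
#' @param level `"animal"` or `"replicate"`.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return one-row data frame of class `group_comparison`: `metric`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `t_stat`, `p_value`, `fold_change`, `level`, `variant`,
#'   `degenerate`.
#' @export
compare_groups <- function(summaries, metric, group_a, group_b,
                           level = c("animal", "replicate"),
                           variant = c("student", "welch")) {
  level <- match.arg(level)
  variant <- match.arg(variant)
  if (!metric %in% names(summaries)) stop("unknown metric column: ", metric)
  for (g in c(group_a, group_b))
    if (!g %in% summaries$group) stop("group not present: ", g)
  va <- group_values(summaries, metric, group_a, level, "undefined value(s)")
  vb <- group_values(summaries, metric, group_b, level, "undefined value(s)")
  if (length(va) < 2L || length(vb) < 2L)
    stop("need >= 2 observations per group at level \"", level, "\"")

  mean_a <- mean(va)
  mean_b <- mean(vb)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  degenerate <- FALSE
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    degenerate <- TRUE
    if (mean_a == mean_b) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean_a - mean_b) * Inf
      p <- 0
    }
  } else {
    tt <- stats::t.test(va, vb, var.equal = (variant == "student"))
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(data.frame(metric = metric, group_a = group_a, group_b = group_b,
                       n_a = length(va), n_b = length(vb),
                       mean_a = mean_a, mean_b = mean_b,
                       sem_a = sem(va), sem_b = sem(vb),
                       t_stat = t_stat, p_value = p,
                       fold_change = if (mean_a != 0) mean_b / mean_a
                       else NA_real_,
                       level = level, variant = variant,
                       degenerate = degenerate, stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' PTZ response: fold changes in speed and distance
#'
#' Compares treated vs untreated animals on swim speed and total distance
#' with the same t-test machinery as [compare_groups()]; fold change =
#' treated mean / untreated mean for each metric. An untreated mean of zero
#' leaves the fold change undefined (NA) with a warning.
#'
#' @param summaries data frame from [summarize_larvae()].
#' @param treated_label,untreated_label group labels.
#' @param level,variant passed to [compare_groups()].
#' @return list with elements `speed` and `distance`, each a
#'   `group_comparison` (fold change = treated / untreated).
#' @export
ptz_response <- function(summaries, treated_label, untreated_label,
                         level = "animal", variant = "student") {
  out <- list(
    speed = compare_groups(summaries, "swim_speed_mm_per_s",
                           group_a = untreated_label, group_b = treated_label,
                           level = level, variant = variant),
    distance = compare_groups(summaries, "total_distance_mm",
                              group_a = untreated_label,
                              group_b = treated_label,
                              level = level, variant = variant))
  for (m in names(out))
    if (is.na(out[[m]]$fold_change))
      warning("untreated mean is zero; ", m, " fold change undefined")
  out
}

#' Write a tracking export CSV
#'
#' @param bins tracking bins data frame.
#' @param path output path.
#' @param seed optional integer seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_tracking_export <- function(bins, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(bins, con, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a table of group comparisons
#'
#' One row per contrast (means, SEM, n, t, p, fold change, level).
#'
#' @param comparisons a `group_comparison` or list of them.
#' @param path output TSV path.
#' @param seed optional integer seed recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparisons, path, seed = NULL) {
  if (inherits(comparisons, "group_comparison"))
    comparisons <- list(comparisons)
  tab <- do.call(rbind, lapply(comparisons, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
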