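# Run-length lifetime statistics for conformations and families.
#
# A lifetime is the duration of a maximal run of identical consecutive
# canonical labels (or families) for one molecule sampled at the recording
# stride: a single frame counts as one stride (the minimum resolvable
# lifetime), each retained frame adds one stride.

#' Run-length encode a state series
#'
#' Extracts the maximal constant runs of each molecule's canonical-label (or
#' family) sequence. Family-level runs are computed on the family sequence,
#' so hydroxyl rotations within a family do not break a family run.
#' Symmetry-variant flips between raw labels in the same orbit share a
#' canonical label and therefore never break a run. Missing (degenerate)
#' frames break runs and are excluded.
#'
#' @param series a \code{state_series}.
#' @param level \code{"label"} (canonical conformation labels) or
#'   \code{"family"}.
#' @return a \code{run_records} data frame with columns \code{molecule},
#'   \code{state}, \code{start_time_ps}, \code{n_frames},
#'   \code{duration_ps}, \code{boundary} (run touches the first or last
#'   frame of the trajectory). Attributes carry \code{level},
#'   \code{stride_ps}, \code{n_frames} and \code{n_molecules}.
#' @export
run_length_encode <- function(series, level = c("label", "family")) {
  level <- match.arg(level)
  seq_mat <- if (level == "label") series$canonical else series$family
  stride <- series$stride_ps
  recs <- vector("list", series$n_molecules)
  for (m in seq_len(series$n_molecules)) {
    s <- seq_mat[m, ]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (!any(keep)) next
    recs[[m]] <- data.frame(
      molecule = m,
      state = r$values[keep],
      start_time_ps = series$time[starts[keep]],
      n_frames = r$lengths[keep],
      duration_ps = r$lengths[keep] * stride,
      boundary = starts[keep] == 1L | ends[keep] == series$n_frames,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (is.null(out)) out <- data.frame(molecule = integer(), state = character(),
                                      start_time_ps = numeric(), n_frames = integer(),
                                      duration_ps = numeric(), boundary = logical())
  structure(out, level = level, stride_ps = stride,
            n_frames = series$n_frames, n_molecules = series$n_molecules,
            class = c("run_records", "data.frame"))
}

#' Filter runs truncated at the trajectory boundaries
#'
#' Runs touching the first or last recorded frame have unknown true length.
#' The default \code{include} keeps them (preserving the conservation
#' property that per-molecule durations sum to the observed span);
#' \code{exclude_boundary} drops them.
#'
#' @param runs a \code{run_records} object from [run_length_encode()].
#' @param policy \code{"include"} or \code{"exclude_boundary"}.
#' @return the filtered \code{run_records}.
#' @export
truncation_policy <- function(runs, policy = c("include", "exclude_boundary")) {
  policy <- match.arg(policy)
  if (policy == "include") return(runs)
  at <- attributes(runs)
  out <- runs[!runs$boundary, , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       at[c("level", "stride_ps", "n_frames", "n_molecules")])
  out
}

#' Average and maximum lifetimes per conformation or family
#'
#' t_av is the arithmetic mean of run durations per state, t_max the
#' maximum. For label-level runs every one of the 25 unique conformations
#' is reported (zero for states never observed); family-level tables report
#' the four families.
#'
#' @param runs a \code{run_records} object.
#' @return a \code{lifetime_table} data frame with columns \code{state},
#'   \code{family} (label level only), \code{n_runs}, \code{t_av_ps},
#'   \code{t_max_ps}.
#' @export
lifetime_table <- function(runs) {
  level <- attr(runs, "level")
  states <- if (identical(level, "family")) .FAMILY_ORDER() else enumerate_unique()$label
  f <- factor(runs$state, levels = states)
  n_runs <- as.integer(table(f))
  t_av <- as.numeric(tapply(runs$duration_ps, f, mean))
  t_max <- as.numeric(tapply(runs$duration_ps, f, max))
  t_av[is.na(t_av)] <- 0
  t_max[is.na(t_max)] <- 0
  out <- data.frame(state = states, n_runs = n_runs,
                    t_av_ps = t_av, t_max_ps = t_max, stringsAsFactors = FALSE)
  if (!identical(level, "family")) {
    out <- cbind(out[, "state", drop = FALSE],
                 family = family_of(states),
                 out[, c("n_runs", "t_av_ps", "t_max_ps")])
  }
  structure(out, level = level,
            class = c("lifetime_table", "data.frame"))
}

#' @export
print.lifetime_table <- function(x, digits = 1, ...) {
  cat(sprintf("Lifetime statistics (%s level)\n", attr(x, "level")))
  shown <- as.data.frame(x)
  shown$t_av_ps <- round(shown$t_av_ps, digits)
  print.data.frame(shown[shown$n_runs > 0L, ], row.names = FALSE)
  invisible(x)
}

#' Occupancy and lifetime summary per conformation and per family
#'
#' Combines [occupancy()] with [lifetime_table()] at both levels into the
#' standard reporting layout: per conformation its content phi (percent of
#' all configurations), average and maximum lifetime; per family the pooled
#' phi and family lifetimes.
#'
#' @param series a \code{state_series}.
#' @param policy boundary-run policy passed to [truncation_policy()].
#' @return a \code{conformation_summary}: list of data frames \code{labels}
#'   and \code{families}.
#' @export
conformation_summary <- function(series, policy = "include") {
  occ <- occupancy(series)
  lt_lab <- lifetime_table(truncation_policy(run_length_encode(series, "label"), policy))
  lt_fam <- lifetime_table(truncation_policy(run_length_encode(series, "family"), policy))
  labels <- cbind(occ$labels,
                  lt_lab[match(occ$labels$label, lt_lab$state),
                         c("n_runs", "t_av_ps", "t_max_ps")])
  rownames(labels) <- NULL
  families <- cbind(occ$families,
                    lt_fam[match(occ$families$family, lt_fam$state),
                           c("n_runs", "t_av_ps", "t_max_ps")])
  rownames(families) <- NULL
  structure(list(labels = labels, families = families, n_conf = occ$n_conf,
                 missing_phi = occ$missing_phi),
            class = "conformation_summary")
}

#' @export
print.conformation_summary <- function(x, ...) {
  cat(sprintf("Conformational composition and lifetimes (N_conf = %d)\n", x$n_conf))
  shown <- x$labels[x$labels$count > 0L, ]
  shown$phi <- round(shown$phi, 2)
  shown$t_av_ps <- round(shown$t_av_ps, 1)
  print.data.frame(shown, row.names = FALSE)
  cat("Families:\n")
  fam <- x$families
  fam$phi <- round(fam$phi, 2)
  fam$t_av_ps <- round(fam$t_av_ps, 1)
  print.data.frame(fam, row.names = FALSE)
  invisible(x)
}

#' Export summary tables as CSV
#'
#' Writes the per-conformation table (phi, t_av rounded to 0.1 ps, t_max)
#' and the per-family table as two CSV files with a common prefix
#' (\code{<prefix>_labels.csv}, \code{<prefix>_families.csv}). Full
#' precision is kept in the returned object; the files round t_av to 0.1 ps
#' and phi to 0.01 percent for reporting.
#'
#' @param summary a \code{conformation_summary}.
#' @param prefix output path prefix.
#' @param ascii write labels with the ASCII prime alias.
#' @return character vector of the two paths, invisibly.
#' @export
write_summary_csv <- function(summary, prefix, ascii = FALSE) {
  paths <- paste0(prefix, c("_labels.csv", "_families.csv"))
  lab <- summary$labels
  fam <- summary$families
  lab$phi <- round(lab$phi, 2); lab$t_av_ps <- round(lab$t_av_ps, 1)
  fam$phi <- round(fam$phi, 2); fam$t_av_ps <- round(fam$t_av_ps, 1)
  if (ascii) {
    lab$label <- gsub(.PRIME, "p", lab$label, fixed = TRUE)
    lab$family <- gsub(.PRIME, "p", lab$family, fixed = TRUE)
    fam$family <- gsub(.PRIME, "p", fam$family, fixed = TRUE)
  }
  utils::write.csv(lab, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(fam, paths[2L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
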