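# Joint movement-range statistics from a pose corpus: per-DoF histograms with
# 2000 bins over [-180, 180] degrees (bin width 0.18 degrees), from which the
# working range of every DoF is read off as the smallest contiguous bin span
# holding a required fraction of the corpus mass.

RANGE_BINS <- 2000L
RANGE_LO <- -180
RANGE_HI <- 180

#' Joint movement ranges from a pose corpus
#'
#' Builds a 2000-bin histogram over \[-180, 180\] degrees for each of the 39
#' DoF and reports, per DoF, the smallest contiguous bin span containing at
#' least `coverage` of the corpus mass. `coverage = 1` returns the exact
#' min/max support of the corpus. Deterministic.
#'
#' @param poses A pose table: data frame / tibble with one row per pose and
#'   one column per DoF (degrees), e.g. from [sample_pose_corpus()].
#' @param coverage Fraction of corpus mass the range must contain,
#'   in (0, 1]. Default 0.995 trims stray extreme poses.
#' @return A tibble of class `joint_ranges` with columns `dof`, `joint`,
#'   `axis`, `lo`, `hi` (degrees) and `histogram` (list column of 2000 bin
#'   counts summing to the corpus size).
#' @export
joint_movement_ranges <- function(poses, coverage = 0.995) {
  poses <- tibble::as_tibble(poses)
  if (nrow(poses) < 1L) stop("empty pose corpus", call. = FALSE)
  if (!(coverage > 0 && coverage <= 1)) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  dofs <- names(poses)
  width <- (RANGE_HI - RANGE_LO) / RANGE_BINS
  n <- nrow(poses)
  need <- ceiling(coverage * n)
  rows <- purrr::map(dofs, function(d) {
    x <- poses[[d]]
    if (any(!is.finite(x)) || any(x < RANGE_LO | x > RANGE_HI)) {
      stop("pose angles for ", d, " outside [-180, 180]", call. = FALSE)
    }
    bin <- pmin(RANGE_BINS, pmax(1L, floor((x - RANGE_LO) / width) + 1L))
    counts <- tabulate(bin, nbins = RANGE_BINS)
    if (coverage == 1) {
      lo <- min(x); hi <- max(x)
    } else {
      # two-pointer scan for the narrowest window with >= `need` mass
      cs <- c(0L, cumsum(counts))
      best <- c(1L, RANGE_BINS)
      left <- 1L
      for (right in seq_len(RANGE_BINS)) {
        while (cs[right + 1L] - cs[left] >= need) {
          if (right - left < best[2] - best[1]) best <- c(left, right)
          left <- left + 1L
        }
      }
      lo <- RANGE_LO + (best[1] - 1L) * width
      hi <- RANGE_LO + best[2] * width
    }
    parts <- strsplit(d, "_", fixed = TRUE)[[1]]
    tibble::tibble(dof = d,
                   joint = paste(parts[-length(parts)], collapse = "_"),
                   axis = parts[length(parts)],
                   lo = lo, hi = hi, histogram = list(counts))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("joint_ranges", class(out))
  out
}

#' Default physiological joint ranges
#'
#' Working ranges (degrees) per DoF used when no pose corpus is supplied:
#' hinge-dominant knees and elbows, wide-roaming shoulders and hips, and
#' modest spine/neck mobility. These drive the synthetic pose corpus, the
#' placement sweeps and the motion generators.
#'
#' @param skeleton A skeleton (defaults to the standard 13-joint body).
#' @return A `joint_ranges` tibble (without histograms).
#' @export
default_joint_ranges <- function(skeleton = build_skeleton()) {
  per_joint <- list(
    PV = rbind(c(-25, 25), c(-30, 30), c(-20, 20)),
    LB = rbind(c(-25, 40), c(-25, 25), c(-20, 20)),
    T  = rbind(c(-20, 30), c(-25, 25), c(-20, 20)),
    UB = rbind(c(-20, 30), c(-30, 30), c(-20, 20)),
    NK = rbind(c(-40, 40), c(-50, 50), c(-35, 35)),
    LS = rbind(c(-60, 150), c(-60, 60), c(-50, 120)),
    LE = rbind(c(0, 140), c(-70, 70), c(-10, 10)),
    RS = rbind(c(-60, 150), c(-60, 60), c(-120, 50)),
    RE = rbind(c(0, 140), c(-70, 70), c(-10, 10)),
    LT = rbind(c(-25, 110), c(-35, 35), c(-35, 35)),
    LK = rbind(c(0, 130), c(-15, 15), c(-10, 10)),
    RT = rbind(c(-25, 110), c(-35, 35), c(-35, 35)),
    RK = rbind(c(0, 130), c(-15, 15), c(-10, 10))
  )
  rows <- purrr::map(skeleton$joints, function(jn) {
    m <- per_joint[[jn]]
    tibble::tibble(dof = paste(jn, c("X", "Y", "Z"), sep = "_"),
                   joint = jn, axis = c("X", "Y", "Z"),
                   lo = m[, 1], hi = m[, 2])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("joint_ranges", class(out))
  out
}

range_for <- function(ranges, dof) {
  i <- match(dof, ranges$dof)
  if (is.na(i)) stop("no range for DoF ", dof, call. = FALSE)
  c(ranges$lo[i], ranges$hi[i])
}

#' Read / write pose tables
#'
#' Pose tables are plain CSV: one row per frame, one DoF-named column
#' (`<joint>_<axis>`, degrees).
#'
#' @param path File path.
#' @param poses Pose tibble to write.
#' @export
read_pose_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_pose_table
#' @export
write_pose_table <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pose_table
#' @param ranges A `joint_ranges` tibble.
#' @export
write_joint_ranges <- function(ranges, path) {
  df <- dplyr::select(tibble::as_tibble(ranges), -dplyr::any_of("histogram"))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname read_pose_table
#' @export
read_joint_ranges <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("joint_ranges", class(out))
  out
}
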