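#' Read / write centroided peak lists
#'
#' Peak lists are CSV with header `mz,intensity` and an optional `charge`
#' column. Rows with non-positive m/z or negative intensity are rejected
#' with the offending line numbers.
#'
#' @param path CSV file.
#' @return data.frame with columns `mz`, `intensity` and, if present,
#'   `charge`.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak list ", path, " must have columns mz,intensity[,charge]")
  bad <- which(!is.finite(df$mz) | df$mz <= 0 |
                 !is.finite(df$intensity) | df$intensity < 0)
  if (length(bad))
    stop("invalid peaks in ", path, " at data line(s): ",
         paste(bad, collapse = ", "))
  df[c("mz", "intensity", intersect("charge", names(df)))]
}

#' @rdname read_peaks
#' @param peaks peak data.frame.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' Total-ion-mapping precursor windows
#'
#' Builds the stepped, overlapping precursor isolation windows used for
#' direct-infusion profile quantification: by default 2.8 m/z wide with
#' 0.8 m/z window-to-window overlap (step 2.0), scanning 600-2000.
#'
#' @param range_start,range_end scanned m/z range.
#' @param width window width in m/z (must exceed `overlap`).
#' @param overlap overlap between consecutive windows.
#' @return data.frame with columns `start`, `end`; the last window is the
#'   first whose end reaches `range_end`.
#' @examples
#' w <- tim_windows()  # 700 windows over 600-2000
#' @export
tim_windows <- function(range_start = 600, range_end = 2000,
                        width = 2.8, overlap = 0.8) {
  if (width <= overlap) stop("window width must exceed overlap")
  if (range_end <= range_start) stop("empty m/z range")
  step <- width - overlap
  starts <- range_start
  while (starts[length(starts)] + width < range_end)
    starts <- c(starts, starts[length(starts)] + step)
  data.frame(start = starts, end = starts + width)
}

#' Summed intensity per TIM window
#'
#' @param peaks peak data.frame (`mz`, `intensity`).
#' @param windows as from [tim_windows()].
#' @return `windows` with an added `intensity` column (sum of peaks whose
#'   m/z falls in `[start, end]`; peaks in overlap regions contribute to
#'   both windows).
#' @export
tim_profile <- function(peaks, windows = tim_windows()) {
  windows$intensity <- vapply(seq_len(nrow(windows)), function(i)
    sum(peaks$intensity[peaks$mz >= windows$start[i] &
                          peaks$mz <= windows$end[i]]), numeric(1))
  windows
}

#' Collapse isotope clusters
#'
#' Groups peaks spaced by 1.00336/z (within `tolerance`) into single
#' cluster records so the naturally occurring isotopes of each species are
#' summed into one response. Charge is inferred by trying each hypothesis
#' in `z_hypotheses` and keeping the one that captures the most peaks with
#' the smallest spacing residual (ties toward lower z). Peaks that join no
#' cluster pass through as singletons with `charge = NA` (or their input
#' charge if a `charge` column is present).
#'
#' @param peaks data.frame `mz`, `intensity` (optional `charge`).
#' @param z_hypotheses charge states to try (default 1:4).
#' @param tolerance m/z matching tolerance (default 0.05).
#' @return data.frame with columns `mz` (most intense member), `intensity`
#'   (cluster sum), `charge`, `n_members`.
#' @export
collapse_isotope_clusters <- function(peaks, z_hypotheses = 1:4,
                                      tolerance = 0.05) {
  n <- nrow(peaks)
  out <- list()
  if (n == 0)
    return(data.frame(mz = numeric(), intensity = numeric(),
                      charge = integer(), n_members = integer()))
  used <- rep(FALSE, n)
  ord <- order(-peaks$intensity)
  for (seed in ord) {
    if (used[seed]) next
    best <- NULL
    for (z in sort(z_hypotheses)) {
      d <- MASS_C13C12 / z
      members <- seed
      resid <- numeric()
      for (dir in c(1, -1)) {
        j <- 1
        repeat {
          target <- peaks$mz[seed] + dir * j * d
          cand <- which(!used & abs(peaks$mz - target) <= tolerance)
          cand <- setdiff(cand, members)
          if (!length(cand)) break
          pick <- cand[which.min(abs(peaks$mz[cand] - target))]
          members <- c(members, pick)
          resid <- c(resid, abs(peaks$mz[pick] - target))
          j <- j + 1
        }
      }
      if (length(members) < 2) next
      score <- list(count = length(members), resid = mean(resid), z = z)
      if (is.null(best) || score$count > best$count ||
          (score$count == best$count && score$resid < best$resid - 1e-12)) {
        best <- score; best$members <- members
      }
    }
    if (is.null(best)) {
      chg <- if ("charge" %in% names(peaks)) peaks$charge[seed] else NA_integer_
      out[[length(out) + 1]] <- data.frame(
        mz = peaks$mz[seed], intensity = peaks$intensity[seed],
        charge = as.integer(chg), n_members = 1L)
      used[seed] <- TRUE
    } else {
      m <- best$members
      out[[length(out) + 1]] <- data.frame(
        mz = peaks$mz[m][which.max(peaks$intensity[m])],
        intensity = sum(peaks$intensity[m]),
        charge = as.integer(best$z), n_members = length(m))
      used[m] <- TRUE
    }
  }
  res <- do.call(rbind, out)
  res[order(res$mz), , drop = FALSE]
}

#' Sum charge states per composition
#'
#' Peaks for all charge states of the same glycan are summed for
#' quantification.
#'
#' @param assigned data.frame with at least `composition` (string) and
#'   `intensity` columns.
#' @return data.frame `composition`, `intensity`, aggregated.
#' @export
sum_charge_states <- function(assigned) {
  if (!nrow(assigned))
    return(data.frame(composition = character(), intensity = numeric()))
  agg <- stats::aggregate(intensity ~ composition, data = assigned, FUN = sum)
  agg[order(-agg$intensity), , drop = FALSE]
}

#' Intensity threshold filter
#'
#' Keeps entries whose intensity is at least `fraction` of a reference
#' intensity -- by default the most intense entry of the input, i.e. 3%
#' of the base response. When filtering per-glycan responses of a whole
#' spectrum, pass the MS1 base-peak intensity as `reference` (3% "of the
#' most intense peak detected on MS1"): summed responses of minor
#' glycans legitimately sit below the largest summed response yet above
#' 3% of the base peak.
#'
#' @param x data.frame with an `intensity` column (or a numeric vector).
#' @param fraction threshold fraction (default 0.03).
#' @param reference reference intensity (default `max(intensity)` of the
#'   input).
#' @return the retained subset, same type as the input.
#' @export
threshold_filter <- function(x, fraction = 0.03, reference = NULL) {
  v <- if (is.data.frame(x)) x$intensity else x
  if (!length(v)) return(x)
  if (is.null(reference)) reference <- max(v)
  keep <- v >= fraction * reference
  if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
}

#' Absolute quantification against a co-injected standard
#'
#' With a known amount of permethylated maltotetraose (Dp4) co-injected
#' with a fraction of the glycan pool, absolute analyte amounts follow as
#' `amount_i = (intensity_i / standard_intensity) * standard_amount /
#' spike_fraction`.
#'
#' @param intensities analyte intensities (named vector or data.frame with
#'   `intensity`).
#' @param standard_intensity intensity of the internal-standard peak.
#' @param standard_amount amount of standard co-injected (any unit; the
#'   result inherits it).
#' @param spike_fraction fraction of the glycan pool co-injected with the
#'   standard (default 0.05).
#' @return numeric vector of amounts.
#' @export
quantify_vs_standard <- function(intensities, standard_intensity,
                                 standard_amount, spike_fraction = 0.05) {
  if (!is.numeric(standard_intensity) || length(standard_intensity) != 1 ||
      is.na(standard_intensity) || standard_intensity <= 0)
    stop("internal-standard peak missing or zero; ",
         "fall back to relative-only quantification")
  if (spike_fraction <= 0 || spike_fraction > 1)
    stop("spike_fraction must be in (0, 1]")
  v <- if (is.data.frame(intensities)) stats::setNames(
    intensities$intensity, intensities$composition) else intensities
  (v / standard_intensity) * standard_amount / spike_fraction
}
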