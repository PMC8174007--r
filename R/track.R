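# Frame-to-frame particle linking: squared-distance cost matrix with
# birth/death alternatives, solved as a linear assignment problem.

#' Build the link/birth/death cost matrix for two consecutive frames
#'
#' The (n + m) x (n + m) layout is the standard LAP-tracking completion:
#' the upper-left n x m block holds squared Euclidean distances (um^2)
#' between the n detections of frame t and the m detections of frame t+1,
#' with pairs beyond `max_linking_distance` forbidden; the upper-right and
#' lower-left diagonals hold the death and birth alternative cost
#' `alternative_cost_factor * max_linking_distance^2`; the lower-right
#' auxiliary block is zero wherever the transposed link is admissible so
#' the matrix always has a feasible completion. Forbidden entries carry a
#' large finite cost (attribute `forbidden`).
#'
#' @param dets_t,dets_next Tibbles with `x_um`, `y_um` (may have zero
#'   rows).
#' @param config A [linking_config()].
#' @return Square numeric matrix with attributes `n`, `m`, `alt_cost`,
#'   `forbidden`.
#' @export
build_cost_matrix <- function(dets_t, dets_next, config = linking_config()) {
  stopifnot(inherits(config, "linking_config"))
  n <- nrow(dets_t)
  m <- nrow(dets_next)
  max2 <- config$max_linking_distance^2
  alt <- config$alternative_cost_factor * max2
  forbid <- 1e9 * max(alt, 1)
  cm <- matrix(forbid, n + m, n + m)
  if (n > 0 && m > 0) {
    d2 <- outer(dets_t$x_um, dets_next$x_um, "-")^2 +
      outer(dets_t$y_um, dets_next$y_um, "-")^2
    link <- ifelse(d2 <= max2, d2, forbid)
    cm[seq_len(n), seq_len(m)] <- link
    cm[n + seq_len(m), m + seq_len(n)] <- ifelse(t(link) < forbid, 0, forbid)
  }
  if (n > 0) cm[cbind(seq_len(n), m + seq_len(n))] <- alt # deaths
  if (m > 0) cm[cbind(n + seq_len(m), seq_len(m))] <- alt # births
  structure(cm, n = n, m = m, alt_cost = alt, forbidden = forbid)
}

#' Solve a link/birth/death assignment
#'
#' Minimum-total-cost assignment of the matrix from [build_cost_matrix()]:
#' every detection in frame t is either linked or dies, every detection in
#' frame t+1 is either linked or born.
#'
#' @param cost_matrix Output of [build_cost_matrix()].
#' @return List with `links` (tibble `from`, `to`, `cost`), `deaths` and
#'   `births` (integer index vectors), and `total_cost` = sum of link
#'   costs + alternative cost x (number of births + deaths).
#' @export
solve_lap <- function(cost_matrix) {
  n <- attr(cost_matrix, "n")
  m <- attr(cost_matrix, "m")
  alt <- attr(cost_matrix, "alt_cost")
  assign_col <- lap_solve_dense(unclass(cost_matrix))
  from <- integer(0)
  to <- integer(0)
  if (n > 0) {
    cols <- assign_col[seq_len(n)]
    linked <- which(cols <= m)
    from <- linked
    to <- cols[linked]
  }
  deaths <- setdiff(seq_len(n), from)
  births <- setdiff(seq_len(m), to)
  link_cost <- if (length(from) > 0) {
    cost_matrix[cbind(from, to)]
  } else {
    numeric(0)
  }
  list(
    links = tibble::tibble(from = from, to = to, cost = link_cost),
    deaths = deaths,
    births = births,
    total_cost = sum(link_cost) + alt * (length(deaths) + length(births))
  )
}

#' Link per-frame localizations into tracks
#'
#' Sequential pairwise LAP over consecutive frames: tracks are extended by
#' links, opened by births and closed by deaths. There is no gap closing
#' and no merge/split, so a blink starts a new track. Deterministic given
#' the input.
#'
#' @param localizations Tibble with at least `frame`, `x_um`, `y_um`
#'   (e.g. from [localize_movie()]); extra columns are carried through.
#' @param config A [linking_config()].
#' @param pixel_size,frame_interval Calibration attached to the returned
#'   tracks; default from the localization attributes.
#' @return An `spt_tracks` tibble: `track_id`, then all input columns,
#'   sorted by track and frame.
#' @export
link_movie <- function(localizations, config = linking_config(),
                       pixel_size = NULL, frame_interval = NULL) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(localizations)))
  pixel_size <- pixel_size %||% attr(localizations, "pixel_size") %||% 0.1
  frame_interval <- frame_interval %||%
    attr(localizations, "frame_interval") %||% 0.03
  if (nrow(localizations) == 0) {
    out <- dplyr::bind_cols(
      tibble::tibble(track_id = integer(0)),
      localizations
    )
    return(new_spt_tracks(out, pixel_size, frame_interval))
  }
  localizations <- dplyr::arrange(localizations, .data$frame)
  frames <- seq(min(localizations$frame), max(localizations$frame))
  by_frame <- split(
    localizations,
    factor(localizations$frame, levels = frames)
  )
  next_id <- 0L
  assign_ids <- function(k) {
    ids <- next_id + seq_len(k)
    next_id <<- next_id + k
    ids
  }
  cur <- by_frame[[1]]
  cur_ids <- assign_ids(nrow(cur))
  pieces <- list(dplyr::bind_cols(tibble::tibble(track_id = cur_ids), cur))
  for (t in seq_along(frames)[-1]) {
    nxt <- by_frame[[t]]
    sol <- solve_lap(build_cost_matrix(cur, nxt, config))
    nxt_ids <- integer(nrow(nxt))
    nxt_ids[sol$links$to] <- cur_ids[sol$links$from]
    if (length(sol$births) > 0) {
      nxt_ids[sol$births] <- assign_ids(length(sol$births))
    }
    if (nrow(nxt) > 0) {
      pieces[[t]] <- dplyr::bind_cols(tibble::tibble(track_id = nxt_ids), nxt)
    }
    cur <- nxt
    cur_ids <- nxt_ids
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$track_id, .data$frame)
  new_spt_tracks(out, pixel_size, frame_interval)
}

new_spt_tracks <- function(df, pixel_size, frame_interval) {
  structure(
    tibble::as_tibble(df),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    class = c("spt_tracks", class(tibble::tibble()))
  )
}

#' @export
print.spt_tracks <- function(x, ...) {
  cat(
    "# sptPALM tracks: ", length(unique(x$track_id)), " tracks, ",
    nrow(x), " localizations (",
    attr(x, "pixel_size"), " um/px, ",
    attr(x, "frame_interval"), " s/frame)\n",
    sep = ""
  )
  NextMethod()
}
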