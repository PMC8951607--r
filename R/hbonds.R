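#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen...acceptor triplet is a hydrogen bond when the
#' donor-acceptor distance is at most `d_max` and the hydrogen-donor-
#' acceptor angle at most `angle_max` (the convention of the standard
#' trajectory-analysis tools).
#'
#' @param d_max donor-acceptor distance cutoff, Angstrom.
#' @param angle_max hydrogen-donor-acceptor angle cutoff, degrees.
#' @return list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 3.5, angle_max = 30) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (angle_max <= 0 || angle_max > 90) stop("angle_max must be in (0, 90]")
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-H / acceptor pairs satisfying the geometric criterion,
#' classified by the segments involved: `cp_cp` (peptide-peptide, with a
#' `backbone` flag true when both partners are backbone amide atoms),
#' `cp_water`, `cp_lipid`, `water_water`, or `other`. Donors are hydrogens
#' carrying a `donor_to` reference; acceptors are atoms flagged `acceptor`.
#' Distances use the minimum-image convention when the frame has a box.
#'
#' @param frame a `nanotube_frame`.
#' @param criterion an [hbond_criterion()].
#' @param donors,acceptors optional `atom_id` vectors restricting the
#'   search.
#' @return tibble (donor, hydrogen, acceptor, class, backbone, donor_ring,
#'   acceptor_ring, distance, angle).
#' @export
find_hbonds <- function(frame, criterion = hbond_criterion(),
                        donors = NULL, acceptors = NULL) {
  hyd <- frame[!is.na(frame$donor_to), ]
  acc <- frame[frame$acceptor %in% TRUE, ]
  if (!is.null(donors)) hyd <- hyd[hyd$atom_id %in% donors, ]
  if (!is.null(acceptors)) acc <- acc[acc$atom_id %in% acceptors, ]
  empty <- tibble::tibble(donor = integer(), hydrogen = integer(),
                          acceptor = integer(), class = character(),
                          backbone = logical(), donor_ring = integer(),
                          acceptor_ring = integer(), distance = numeric(),
                          angle = numeric())
  if (nrow(hyd) == 0 || nrow(acc) == 0) {
    warning("empty donor or acceptor selection")
    return(empty)
  }
  don_idx <- match(hyd$donor_to, frame$atom_id)
  don <- frame[don_idx, ]
  box <- frame_box(frame)

  nH <- nrow(hyd); nA <- nrow(acc)
  iH <- rep(seq_len(nH), each = nA)
  iA <- rep(seq_len(nA), nH)
  Dxyz <- frame_coords(don)[iH, , drop = FALSE]
  Hxyz <- frame_coords(hyd)[iH, , drop = FALSE]
  Axyz <- frame_coords(acc)[iA, , drop = FALSE]
  da <- min_image(Axyz - Dxyz, box)
  keep <- rowSums(da^2) <= criterion$d_max^2
  keep <- keep & don$atom_id[iH] != acc$atom_id[iA]
  if (!any(keep)) return(empty)
  iH <- iH[keep]; iA <- iA[keep]; da <- da[keep, , drop = FALSE]
  dh <- min_image(Hxyz[keep, , drop = FALSE] - Dxyz[keep, , drop = FALSE], box)
  ang <- vec_angle_rows(dh, da)
  ok <- ang <= criterion$angle_max
  iH <- iH[ok]; iA <- iA[ok]
  if (length(iH) == 0) return(empty)

  seg_d <- don$segment[iH]; seg_a <- acc$segment[iA]
  cls <- dplyr::case_when(
    seg_d == "cp" & seg_a == "cp" ~ "cp_cp",
    (seg_d == "cp" & seg_a == "water") | (seg_d == "water" & seg_a == "cp") ~ "cp_water",
    (seg_d == "cp" & seg_a == "lipid") | (seg_d == "lipid" & seg_a == "cp") ~ "cp_lipid",
    seg_d == "water" & seg_a == "water" ~ "water_water",
    TRUE ~ "other")
  tibble::tibble(
    donor = don$atom_id[iH], hydrogen = hyd$atom_id[iH],
    acceptor = acc$atom_id[iA], class = cls,
    backbone = don$backbone[iH] & hyd$backbone[iH] & acc$backbone[iA] &
      seg_d == "cp" & seg_a == "cp",
    donor_ring = don$ring[iH], acceptor_ring = acc$ring[iA],
    distance = sqrt(rowSums(da[ok, , drop = FALSE]^2)),
    angle = ang[ok])
}

#' Detect hydrogen bonds over a trajectory
#'
#' @param traj a `nanotube_trajectory`.
#' @param criterion an [hbond_criterion()].
#' @param discard initial time (ps) to drop.
#' @return tibble as [find_hbonds()] with a leading `frame` column; its
#'   `"frames"` attribute lists every analysed frame index (including those
#'   with no bonds) and `"dt"` the frame spacing.
#' @export
hbond_series <- function(traj, criterion = hbond_criterion(), discard = 0) {
  idx <- which(traj$time >= discard)
  res <- purrr::map_dfr(idx, function(t) {
    b <- suppressWarnings(find_hbonds(get_frame(traj, t), criterion))
    if (nrow(b) > 0) b$frame <- t
    b
  })
  if (nrow(res) > 0) res <- dplyr::relocate(res, "frame")
  attr(res, "frames") <- idx
  attr(res, "dt") <- if (length(traj$time) > 1) diff(traj$time[1:2]) else 1
  res
}

filter_class <- function(records, class) {
  if (is.null(class)) return(records)
  if (class == "cp_cp_backbone") {
    records[records$class == "cp_cp" & records$backbone, ]
  } else {
    records[records$class == class, ]
  }
}

ring_pair_label <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  sprintf("%d-%d", lo, hi)
}

#' Per-frame hydrogen-bond counts
#'
#' @param records output of [hbond_series()] (or [find_hbonds()] with a
#'   `frame` column added).
#' @param class one of `"cp_cp"`, `"cp_cp_backbone"`, `"cp_water"`,
#'   `"cp_lipid"`, `"water_water"`, or NULL for all records.
#' @param frames frame indices to report (zero-count frames included);
#'   defaults to the `"frames"` attribute of `records`.
#' @param by_pair break `cp_cp` classes down by ring pair.
#' @return tibble (frame, count) or (frame, pair, count).
#' @export
count_hbonds <- function(records, class = NULL, frames = NULL, by_pair = FALSE) {
  frames <- frames %||% attr(records, "frames") %||% sort(unique(records$frame))
  rec <- filter_class(records, class)
  if (by_pair) {
    rec$pair <- ring_pair_label(rec$donor_ring, rec$acceptor_ring)
    cnt <- dplyr::count(rec, .data$frame, .data$pair, name = "count")
    pairs <- sort(unique(cnt$pair))
    full <- tidyr::expand_grid(frame = frames, pair = pairs)
    out <- dplyr::left_join(full, cnt, by = c("frame", "pair"))
  } else {
    cnt <- dplyr::count(rec, .data$frame, name = "count")
    out <- dplyr::left_join(tibble::tibble(frame = frames), cnt, by = "frame")
  }
  out$count[is.na(out$count)] <- 0L
  out
}

#' Distribution summary of per-frame counts
#'
#' @param counts output of [count_hbonds()].
#' @return tibble with mean, median and quartiles of the per-frame count
#'   (per pair when present).
#' @export
count_summary <- function(counts) {
  g <- if ("pair" %in% names(counts)) dplyr::group_by(counts, .data$pair) else counts
  dplyr::summarise(g, mean = mean(.data$count),
                   median = stats::median(.data$count),
                   q25 = stats::quantile(.data$count, 0.25),
                   q75 = stats::quantile(.data$count, 0.75),
                   .groups = "drop")
}

#' Hydrogen-bond lifetimes (continuous definition)
#'
#' A bond instance is a maximal run of frames over which a given
#' donor-hydrogen-acceptor triplet is present, allowing interruptions of at
#' most `gap_tolerance` frames; its lifetime is the spanned number of
#' frames times the frame spacing. This is the continuous estimator; the
#' intermittent (autocorrelation) lifetime is deliberately not implemented.
#'
#' @param records output of [hbond_series()].
#' @param class optional class filter as in [count_hbonds()].
#' @param dt frame spacing, ps; defaults to the records' `"dt"` attribute.
#' @param gap_tolerance maximum gap (frames) bridged within one instance.
#' @return tibble of instances (donor, hydrogen, acceptor, class, pair,
#'   first, last, lifetime).
#' @export
hbond_lifetimes <- function(records, class = NULL, dt = NULL, gap_tolerance = 0) {
  frames_attr <- attr(records, "frames")
  nfr <- length(frames_attr %||% unique(records$frame))
  if (nfr < 2) stop("lifetimes undefined for a single frame")
  dt <- dt %||% attr(records, "dt") %||% 1
  rec <- filter_class(records, class)
  if (nrow(rec) == 0)
    return(tibble::tibble(donor = integer(), hydrogen = integer(),
                          acceptor = integer(), class = character(),
                          pair = character(), first = integer(),
                          last = integer(), lifetime = numeric()))
  rec$pair <- ring_pair_label(rec$donor_ring, rec$acceptor_ring)
  rec <- dplyr::arrange(rec, .data$donor, .data$hydrogen, .data$acceptor,
                        .data$frame)
  rec <- dplyr::group_by(rec, .data$donor, .data$hydrogen, .data$acceptor,
                         .data$class, .data$pair)
  rec <- dplyr::mutate(rec, instance = cumsum(
    c(TRUE, diff(.data$frame) > gap_tolerance + 1)))
  out <- dplyr::summarise(dplyr::group_by(rec, .data$instance, .add = TRUE),
                          first = min(.data$frame), last = max(.data$frame),
                          .groups = "drop")
  out$lifetime <- (out$last - out$first + 1) * dt
  out$instance <- NULL
  out
}

#' Mean lifetime per class (and optionally ring pair)
#'
#' @param instances output of [hbond_lifetimes()].
#' @param by_pair also group by ring pair.
#' @return tibble (class, \[pair,\] n_instances, mean_lifetime, sd_lifetime).
#' @export
lifetime_summary <- function(instances, by_pair = FALSE) {
  g <- if (by_pair) dplyr::group_by(instances, .data$class, .data$pair)
       else dplyr::group_by(instances, .data$class)
  dplyr::summarise(g, n_instances = dplyr::n(),
                   mean_lifetime = mean(.data$lifetime),
                   sd_lifetime = sd_or_zero(.data$lifetime),
                   .groups = "drop")
}
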