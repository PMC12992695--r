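#' Skeleton configuration
#'
#' Declares which markers, joint-angle triples and reference marker the
#' kinematic feature engine uses, and which feature categories to compute.
#' Angle triples are `(A, B, C)` with the angle measured at `B`.
#'
#' @param markers markers whose point features (speed/acceleration) are
#'   computed.
#' @param angles named list of character triples `c(a, b, c)`.
#' @param reference_marker marker used for forward movement and as the
#'   default height marker (typically the metatarsophalangeal joint / toe).
#' @param height_markers markers whose z height is a feature (default:
#'   the reference marker).
#' @param features character subset of
#'   `c("speed", "acceleration", "tangential_acceleration", "angle",
#'   "angle_velocity", "angle_acceleration", "height", "forward_movement")`.
#' @return object of class `skeleton_config`.
#' @export
skeleton_config <- function(markers, angles = list(), reference_marker,
                            height_markers = reference_marker,
                            features = c("speed", "acceleration", "angle",
                                         "angle_velocity",
                                         "angle_acceleration", "height")) {
  all_feats <- c("speed", "acceleration", "tangential_acceleration", "angle",
                 "angle_velocity", "angle_acceleration", "height",
                 "forward_movement")
  stopifnot(all(features %in% all_feats))
  for (tr in angles)
    if (length(tr) != 3L)
      abort2("each angle entry must be a (A, B, C) triple",
             "phenogait_config_error")
  structure(list(markers = markers, angles = angles,
                 reference_marker = reference_marker,
                 height_markers = height_markers, features = features),
            class = "skeleton_config")
}

#' Read a skeleton configuration from YAML
#' @param path YAML file with fields markers, angles, reference_marker,
#'   features.
#' @export
read_skeleton_config <- function(path) {
  y <- yaml::read_yaml(path)
  skeleton_config(unlist(y$markers),
                  lapply(y$angles, unlist),
                  y$reference_marker,
                  height_markers = unlist(y$height_markers) %||%
                    y$reference_marker,
                  features = unlist(y$features))
}

#' Rodent hindlimb skeleton fixture
#'
#' One consistent reading of the bilateral hindlimb marker set (iliac
#' crest, hip, knee, ankle, metatarsophalangeal joint per side) yielding 36
#' features: speed and acceleration for hip/knee/ankle/mtp, angle plus its
#' first two derivatives at hip/knee/ankle, and mtp height, per side.
#'
#' @return a `skeleton_config`.
#' @export
rodent_skeleton <- function() {
  side <- function(s) {
    mk <- paste(c("crest", "hip", "knee", "ankle", "mtp"), s, sep = "_")
    names(mk) <- c("crest", "hip", "knee", "ankle", "mtp")
    mk
  }
  L <- side("L"); R <- side("R")
  ang <- function(m) list(
    c(m[["crest"]], m[["hip"]], m[["knee"]]),
    c(m[["hip"]], m[["knee"]], m[["ankle"]]),
    c(m[["knee"]], m[["ankle"]], m[["mtp"]]))
  angles <- c(ang(L), ang(R))
  names(angles) <- c("hip_L", "knee_L", "ankle_L", "hip_R", "knee_R", "ankle_R")
  skeleton_config(
    markers = c(L[-1], R[-1]),
    angles = angles,
    reference_marker = "mtp_L",
    height_markers = c("mtp_L", "mtp_R"),
    features = c("speed", "acceleration", "angle", "angle_velocity",
                 "angle_acceleration", "height"))
}

#' Joint angle at the middle marker of a triple
#'
#' Angle at `b` between limb vectors `(a - b)` and `(c - b)`, in degrees,
#' via the arccosine of the normalized dot product, hence in `[0, 180]`.
#'
#' @param a,b,c numeric T x 3 matrices of equal length.
#' @return numeric vector of angles in degrees.
#' @export
joint_angle <- function(a, b, c) {
  a <- as.matrix(a); b <- as.matrix(b); c <- as.matrix(c)
  stopifnot(nrow(a) == nrow(b), nrow(b) == nrow(c))
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  bad <- which(nu < 1e-12 | nv < 1e-12)
  if (length(bad))
    abort2(paste0("zero-length limb vector at frame(s) ",
                  paste(head(bad, 5), collapse = ", ")),
           "phenogait_geometry_error")
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Direction of travel along the runway axis
#'
#' @param traj a [marker_trajectories].
#' @param reference_marker marker whose net x displacement defines direction.
#' @param min_displacement minimum |net displacement| in mm below which the
#'   direction is ambiguous.
#' @return `+1` or `-1`.
#' @export
derive_travel_direction <- function(traj, reference_marker,
                                    min_displacement = 10) {
  p <- traj$positions[[reference_marker]]
  if (is.null(p))
    abort2(paste("unknown marker", reference_marker), "phenogait_config_error")
  x <- p[, 1]
  x <- x[!is.na(x)]
  dx <- x[length(x)] - x[1]
  if (abs(dx) < min_displacement)
    abort2(sprintf("net displacement %.3g mm below minimum %.3g mm", dx,
                   min_displacement), "phenogait_ambiguous_direction_error")
  sign(dx)
}

# Linear interpolation of short gaps; a marker with any gap longer than
# max_gap frames (or leading/trailing gaps) is rejected for the run.
fill_gaps <- function(traj, max_gap = 10) {
  rejected <- character(0)
  for (m in traj$marker_names) {
    p <- traj$positions[[m]]
    if (!anyNA(p)) next
    na_row <- rowSums(is.na(p)) > 0
    r <- rle(na_row)
    if (any(r$values & r$lengths > max_gap) || na_row[1] ||
        na_row[length(na_row)]) {
      rejected <- c(rejected, m)
      next
    }
    for (j in 1:3) p[, j] <- zoo::na.approx(p[, j], na.rm = FALSE)
    traj$positions[[m]] <- p
  }
  traj$positions[rejected] <- NULL
  traj$marker_names <- setdiff(traj$marker_names, rejected)
  attr(traj, "rejected_markers") <- rejected
  traj
}

first_diff <- function(x) {
  d <- diff(x)
  c(d[1], d)
}

#' Sliding-window kinematic features
#'
#' Computes the per-frame kinematic feature matrix: a 2-frame window with a
#' 1-frame hop, so the feature rate equals the frame rate. Speed is the
#' first-difference displacement magnitude times the frame rate (mm/s);
#' acceleration the second-difference magnitude times rate squared;
#' tangential acceleration the derivative of speed. Joint angles (degrees)
#' and their first two derivatives come from the configured triples. Height
#' is the z coordinate of the reference marker; forward movement is its
#' per-frame x displacement, sign-normalized so travel direction is
#' positive. Derivative features are back-filled at the first frame(s) so
#' the feature length equals the frame count.
#'
#' @param traj a [marker_trajectories] (gaps up to `max_gap` frames are
#'   linearly interpolated; markers with longer gaps are dropped for the
#'   run).
#' @param skeleton a [skeleton_config].
#' @param max_gap maximum interpolatable gap, frames.
#' @return a [feature_matrix] at the frame rate.
#' @export
compute_kinematic_features <- function(traj, skeleton, max_gap = 10) {
  if (traj$n_frames < 3)
    abort2("need at least 3 frames", "phenogait_insufficient_data_error")
  traj <- fill_gaps(traj, max_gap)
  fr <- traj$frame_rate
  feats <- list()
  want <- skeleton$features
  for (m in intersect(skeleton$markers, traj$marker_names)) {
    p <- traj$positions[[m]]
    d <- apply(p, 2, first_diff)
    speed <- sqrt(rowSums(d^2)) * fr
    if ("speed" %in% want) feats[[paste0("speed ", m)]] <- speed
    if ("acceleration" %in% want) {
      dd <- apply(apply(p, 2, diff), 2, diff)
      acc <- sqrt(rowSums(dd^2)) * fr^2
      feats[[paste0("acceleration ", m)]] <- c(acc[1], acc[1], acc)
    }
    if ("tangential_acceleration" %in% want)
      feats[[paste0("tangential_acceleration ", m)]] <- first_diff(speed) * fr
  }
  for (an in names(skeleton$angles)) {
    tr <- skeleton$angles[[an]]
    if (!all(tr %in% traj$marker_names)) next
    ang <- joint_angle(traj$positions[[tr[1]]], traj$positions[[tr[2]]],
                       traj$positions[[tr[3]]])
    if ("angle" %in% want) feats[[paste0("angle ", an)]] <- ang
    if ("angle_velocity" %in% want)
      feats[[paste0("angle_velocity ", an)]] <- first_diff(ang) * fr
    if ("angle_acceleration" %in% want)
      feats[[paste0("angle_acceleration ", an)]] <-
        first_diff(first_diff(ang) * fr) * fr
  }
  if ("height" %in% want)
    for (hm in intersect(skeleton$height_markers, traj$marker_names))
      feats[[paste0("height ", hm)]] <- traj$positions[[hm]][, 3]
  refm <- skeleton$reference_marker
  if (refm %in% traj$marker_names) {
    ref <- traj$positions[[refm]]
    if ("forward_movement" %in% want) {
      dir <- tryCatch(derive_travel_direction(traj, refm),
                      phenogait_ambiguous_direction_error = function(e) 1)
      feats[[paste0("forward_movement ", refm)]] <-
        first_diff(ref[, 1]) * dir
    }
  }
  if (!length(feats))
    abort2("no computable features for this trajectory",
           "phenogait_insufficient_data_error")
  vals <- do.call(cbind, feats)
  colnames(vals) <- names(feats)
  feature_matrix(vals, times = (seq_len(traj$n_frames) - 1) / fr, rate = fr,
                 run_id = traj$run_id, subject_id = traj$subject_id,
                 day_id = traj$day_id)
}
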