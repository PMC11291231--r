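## Shank-fixed right-handed frame, right leg: x anterior, y superior,
## z lateral; ankle angle theta in rad, dorsiflexion positive; the foot
## (and with it the calcaneal insertion) rotates about the z axis through
## the ankle joint center.

.ts_muscles <- c("SOL", "GM", "GL")
.twist_classes <- c("none", "low", "medium", "high")
.twist_scales <- c(1.0, 1.5, 2.0)

#' Build subtendon insertion points for a twist class
#'
#' Places the calcaneal insertion point of each triceps surae actuator.  For
#' `twist_class = "none"` all three insertions coincide with the Achilles
#' tendon midpoint (the generic single-insertion model).  For the low, medium
#' and high twist classes each subtendon is offset from the midpoint by the
#' class's row of `base_offsets`; the enlargement factor `scale` multiplies
#' every offset vector (1.5 and 2.0 emulate tendons whose insertions lie 50%
#' and 100% further from the midpoint).
#'
#' @param twist_class One of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @param scale Enlargement factor, one of 1.0, 1.5, 2.0.
#' @param base_offsets Data frame with columns `muscle`, `twist_class`, `dx`,
#'   `dy`, `dz` (m), giving the scale-1 offset of each subtendon insertion
#'   from the Achilles midpoint; defaults to the table shipped with the
#'   package (see [default_twist_offsets()]).
#' @param at_midpoint Achilles tendon midpoint at the calcaneal insertion,
#'   3D coordinates (m) in the shank frame at neutral ankle.
#' @return An object of class `insertion_set`: list with `twist_class`,
#'   `scale`, `at_midpoint` and `points`, a named list of per-muscle 3D
#'   insertion coordinates.
#' @export
#' @examples
#' build_insertions("low", 2.0)
build_insertions <- function(twist_class, scale = 1.0,
                             base_offsets = default_twist_offsets(),
                             at_midpoint = c(-0.066, -0.035, -0.003)) {
  if (!is.character(twist_class) || length(twist_class) != 1L ||
      !twist_class %in% .twist_classes)
    stop("unknown twist_class '", twist_class, "'; must be one of: ",
         paste(.twist_classes, collapse = ", "))
  if (!is.numeric(scale) || length(scale) != 1L ||
      !any(abs(scale - .twist_scales) < 1e-12))
    stop("unknown scale ", scale, "; must be one of: ",
         paste(.twist_scales, collapse = ", "))
  stopifnot(is.numeric(at_midpoint), length(at_midpoint) == 3L)
  pts <- list()
  for (m in .ts_muscles) {
    off <- c(0, 0, 0)
    if (twist_class != "none") {
      row <- base_offsets[base_offsets$muscle == m &
                          base_offsets$twist_class == twist_class, ,
                          drop = FALSE]
      if (nrow(row) != 1L)
        stop("base_offsets must contain exactly one row for (", m, ", ",
             twist_class, ")")
      off <- as.numeric(row[1, c("dx", "dy", "dz")])
    }
    pts[[m]] <- at_midpoint + scale * off
  }
  structure(list(twist_class = twist_class, scale = scale,
                 at_midpoint = at_midpoint, points = pts),
            class = "insertion_set")
}

#' Default subtendon twist offset table
#'
#' Reads the offset table shipped with the package
#' (`extdata/twist_offsets.csv`).  The table is a synthetic stand-in for
#' subject-specific subtendon midpoints: the three subtendons are arranged on
#' an ellipse in the calcaneal cross-section (mediolateral semi-axis 5 mm,
#' anteroposterior 1.5 mm, vertical 1 mm) and the arrangement is rotated by
#' 15, 40 and 65 degrees for the low, medium and high twist classes, rotating
#' the soleus subtendon from medial toward lateral as twist increases.
#' Offsets are kept small in the sagittal plane so that induced moment-arm
#' changes stay in the low-millimetre range.
#'
#' @return Data frame with columns `muscle`, `twist_class`, `dx`, `dy`, `dz`
#'   (m).
#' @export
default_twist_offsets <- function() {
  path <- system.file("extdata", "twist_offsets.csv", package = "tsforce",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Muscle path model
#'
#' A reduced polyline stand-in for a musculoskeletal model muscle path:
#' origin and via point are shank-fixed, the insertion is foot-fixed and
#' rotates with the ankle.  `const_offset` adds proximal path length not
#' represented by the polyline (set during model calibration), and
#' `knee_arm` shifts the path length linearly with knee flexion for the
#' bi-articular gastrocnemii.
#'
#' @param origin,via 3D coordinates (m), shank frame.
#' @param insertion 3D coordinates (m) of the calcaneal insertion at neutral
#'   ankle.
#' @param joint_center Ankle joint center, 3D coordinates (m).
#' @param const_offset Constant added to the polyline length (m).
#' @param knee_arm Path-length change per radian of knee flexion (m/rad);
#'   knee flexion shortens the gastrocnemii, so positive values shorten the
#'   path.
#' @return An object of class `path_model`.
#' @export
path_model <- function(origin, via, insertion,
                       joint_center = c(0, 0, 0), const_offset = 0,
                       knee_arm = 0) {
  stopifnot(length(origin) == 3L, length(via) == 3L, length(insertion) == 3L,
            length(joint_center) == 3L, is.finite(const_offset),
            is.finite(knee_arm))
  structure(list(origin = as.numeric(origin), via = as.numeric(via),
                 insertion = as.numeric(insertion),
                 joint_center = as.numeric(joint_center),
                 const_offset = const_offset, knee_arm = knee_arm),
            class = "path_model")
}

.rot_insertion <- function(theta, path) {
  p <- path$insertion - path$joint_center
  ct <- cos(theta); st <- sin(theta)
  path$joint_center +
    c(ct * p[1] - st * p[2], st * p[1] + ct * p[2], p[3])
}

#' Musculotendon length
#'
#' Polyline length origin-via-insertion with the insertion rotated by the
#' ankle angle, plus the path's constant offset and knee term.  Strictly
#' increasing in dorsiflexion for plantarflexor paths.
#'
#' @param theta Ankle angle (rad, dorsiflexion positive), within +/- 60 deg.
#' @param path A [path_model()].
#' @param knee Knee flexion angle (rad), default 0 (straight).
#' @return Length (m).
#' @export
mtu_length <- function(theta, path, knee = 0) {
  stopifnot(inherits(path, "path_model"))
  if (any(!is.finite(theta)) || any(abs(theta) > pi / 3 + 1e-9))
    stop("theta must be finite and within +/- 60 degrees")
  vapply(theta, function(th) {
    q <- .rot_insertion(th, path)
    sqrt(sum((path$origin - path$via)^2)) + sqrt(sum((path$via - q)^2)) +
      path$const_offset - path$knee_arm * knee
  }, numeric(1))
}

#' Tendon-excursion moment arm
#'
#' Plantarflexion moment arm of a path about the ankle, computed as the
#' derivative of musculotendon length with respect to the dorsiflexion-
#' positive ankle angle (equivalently minus the derivative with respect to
#' the plantarflexion angle).  Positive for plantarflexors: a muscle force F
#' produces the plantarflexion moment `r * F`.
#'
#' @inheritParams mtu_length
#' @return Moment arm (m).
#' @export
moment_arm <- function(theta, path, knee = 0) {
  stopifnot(inherits(path, "path_model"))
  if (any(!is.finite(theta)) || any(abs(theta) > pi / 3 + 1e-9))
    stop("theta must be finite and within +/- 60 degrees")
  vapply(theta, function(th) {
    q <- .rot_insertion(th, path)
    seg <- q - path$via
    len <- sqrt(sum(seg^2))
    p <- q - path$joint_center
    dq <- c(-p[2], p[1], 0)  # d(R(theta) p)/dtheta
    sum(seg * dq) / len
  }, numeric(1))
}
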