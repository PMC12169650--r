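# Rigid base-pair / base-step parameter algebra.
#
# The six descriptors relating two orientation frames follow the mid-frame
# (hinge-axis) construction used by the 3DNA family of tools: the two frame
# z-axes are symmetrically rotated onto their common bisector plane about the
# hinge axis z1 x z2, twist is measured between the corrected x-axes, the
# bending angle Gamma is distributed onto roll/tilt by the phase angle phi
# between the hinge and the mid-frame y-axis, and translations are expressed
# in the mid-frame. The decomposition has an exact closed-form inverse which
# the duplex builder uses, so build -> extract is an identity to numerical
# precision.

# decompose relative rotation/translation of frame2 w.r.t. frame1.
# returns rot = c(rx, ry, rz) degrees (tilt/buckle, roll/propeller,
# twist/opening), trans = c(x, y, z) Angstrom, and the mid frame.
frames_to_params <- function(f1, f2) {
  z1 <- f1$R[, 3]
  z2 <- f2$R[, 3]
  cg <- clamp1(sum(z1 * z2))
  gamma <- acos(cg)
  if (rad2deg(gamma) >= 179)
    stop("degenerate hinge: frames bent by >= 179 degrees")
  if (gamma < 1e-7 || vnorm(cross3(z1, z2)) < 1e-9) {
    zm <- z1
    x1p <- f1$R[, 1]
    x2p <- f2$R[, 1]
    twist <- signed_angle(x1p, x2p, zm)
    xm <- unitv(x1p + x2p)
    ym <- unitv(cross3(zm, xm))
    roll <- 0
    tilt <- 0
  } else {
    hinge <- unitv(cross3(z1, z2))
    R1p <- rot_axis(hinge, gamma / 2) %*% f1$R
    R2p <- rot_axis(hinge, -gamma / 2) %*% f2$R
    zm <- R1p[, 3]
    twist <- signed_angle(R1p[, 1], R2p[, 1], zm)
    if (abs(abs(rad2deg(twist)) - 180) < 1) {
      stop("degenerate hinge: twist within 1 degree of 180")
    }
    xm <- unitv(R1p[, 1] + R2p[, 1])
    ym <- unitv(cross3(zm, xm))
    phi <- signed_angle(hinge, ym, zm)
    roll <- gamma * cos(phi)
    tilt <- gamma * sin(phi)
  }
  Rm <- cbind(xm, ym, zm)
  om <- (f1$o + f2$o) / 2
  trans <- as.numeric(t(Rm) %*% (f2$o - f1$o))
  list(rot = rad2deg(c(tilt, roll, twist)),
       trans = trans,
       mid = new_frame(Rm, om))
}

# exact inverse of frames_to_params: given frame1 and parameters, construct
# frame2 and the mid frame.
params_to_frames <- function(f1, rot_deg, trans) {
  tilt <- deg2rad(rot_deg[1])
  roll <- deg2rad(rot_deg[2])
  twist <- deg2rad(rot_deg[3])
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  Rrel <- rot_z(twist / 2 - phi) %*% rot_y(gamma) %*% rot_z(twist / 2 + phi)
  Rmrel <- rot_z(twist / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  R2 <- f1$R %*% Rrel
  Rm <- f1$R %*% Rmrel
  o2 <- f1$o + as.numeric(Rm %*% trans)
  list(f2 = new_frame(R2, o2), mid = new_frame(Rm, (f1$o + o2) / 2))
}

param_names_step <- c("tilt", "roll", "twist", "shift", "slide", "rise")
param_names_pair <- c("buckle", "propeller", "opening",
                      "shear", "stretch", "stagger")

#' Base-pair parameters from two base frames
#'
#' Computes the six base-pair parameters (buckle, propeller, opening in
#' degrees; shear, stretch, stagger in Angstrom) relating a Watson base frame
#' to its complementary Crick base frame, together with the pair (mid) frame.
#' The Crick frame is flipped 180 degrees about its own x-axis before the
#' mid-frame decomposition, so two coincident ideal bases give all-zero
#' parameters.
#'
#' @param frame_w Watson base frame (`list(R, o)` as returned by
#'   [fit_base_frame()]).
#' @param frame_c Crick base frame.
#' @param flip_crick Flip the Crick frame about its x-axis first (default
#'   `TRUE`; set `FALSE` if the supplied frame is already flipped).
#' @return `list(params, frame)`: named numeric vector of the six parameters
#'   and the base-pair frame.
#' @export
pair_parameters <- function(frame_w, frame_c, flip_crick = TRUE) {
  fc <- if (flip_crick) flip_frame(frame_c) else frame_c
  dec <- frames_to_params(fc, frame_w)
  p <- c(dec$rot, dec$trans)
  names(p) <- param_names_pair
  list(params = p, frame = dec$mid)
}

#' Base-step parameters from two consecutive base-pair frames
#'
#' Computes the six base-step parameters (tilt, roll, twist in degrees;
#' shift, slide, rise in Angstrom) relating base-pair frame i to frame i+1
#' via the mid-step frame.
#'
#' @param pair_frame_i,pair_frame_j Consecutive base-pair frames (5' to 3'
#'   on the Watson strand).
#' @return `list(params, frame)` with the six named step parameters and the
#'   mid-step frame.
#' @export
step_parameters <- function(pair_frame_i, pair_frame_j) {
  dec <- frames_to_params(pair_frame_i, pair_frame_j)
  p <- c(dec$rot, dec$trans)
  names(p) <- param_names_step
  list(params = p, frame = dec$mid)
}

#' Compose frames from rigid-base parameters
#'
#' Exact inverse of [step_parameters()] / [pair_parameters()]. Given a
#' reference frame and six parameters, reconstructs the second frame (and the
#' mid frame). For `type = "step"` the reference is base-pair frame i and the
#' result is base-pair frame i+1; for `type = "pair"` the reference is the
#' flipped Crick base frame and the result is the Watson base frame.
#'
#' @param frame1 Reference frame.
#' @param params Named or positional numeric vector: three angles (degrees)
#'   then three translations (Angstrom), in the conventional order
#'   (tilt, roll, twist, shift, slide, rise) or (buckle, propeller, opening,
#'   shear, stretch, stagger).
#' @param type `"step"` or `"pair"` (labels only; the algebra is shared).
#' @return `list(f2, mid)` frames.
#' @export
compose_frames <- function(frame1, params, type = c("step", "pair")) {
  type <- match.arg(type)
  stopifnot(length(params) == 6)
  params_to_frames(frame1, params[1:3], params[4:6])
}

# Split a pair/mid frame into the two constituent frames given the six
# parameters (inverse of the mid-frame construction used by the builder).
# Returns f1 (flipped-Crick for pairs / pair i for steps) and f2 (Watson /
# pair i+1).
split_mid_frame <- function(mid, params) {
  tilt <- deg2rad(params[1])
  roll <- deg2rad(params[2])
  twist <- deg2rad(params[3])
  trans <- params[4:6]
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  Rmrel <- rot_z(twist / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  Rrel <- rot_z(twist / 2 - phi) %*% rot_y(gamma) %*% rot_z(twist / 2 + phi)
  R1 <- mid$R %*% t(Rmrel)
  R2 <- R1 %*% Rrel
  dvec <- as.numeric(mid$R %*% trans)
  o1 <- mid$o - dvec / 2
  o2 <- mid$o + dvec / 2
  list(f1 = new_frame(R1, o1), f2 = new_frame(R2, o2))
}
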