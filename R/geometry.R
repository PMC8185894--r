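# Continuous ellipse / ellipsoid geometry used by the generator's ground
# truth. All coordinates are in micron.

# Rotate 2D points by angle phi (counter-clockwise).
rot2 <- function(xy, phi) {
  cbind(cos(phi) * xy[, 1] - sin(phi) * xy[, 2],
        sin(phi) * xy[, 1] + cos(phi) * xy[, 2])
}

# Distance from the centre to the boundary of an axis-aligned ellipse /
# ellipsoid along unit direction `dir` (in the ellipse frame).
rayBoundaryDistance <- function(dir, axes) {
  1 / sqrt(sum((dir / axes)^2))
}

# Minimum distance from an interior point `p` (ellipse frame, length 2 or
# 3) to the boundary of the axis-aligned ellipse/ellipsoid with semi-axes
# `axes`. Solved via the Lagrange condition: the closest boundary point is
# x_i = a_i^2 p_i / (a_i^2 + t) with t the root of
# sum((a_i p_i / (a_i^2 + t))^2) = 1 in (-min(a)^2, 0]. Coordinates are
# nudged off exact zero so the bracketing term keeps its pole.
interiorBoundaryDistance <- function(p, axes) {
  stopifnot(length(p) == length(axes))
  q <- pmax(abs(p), 1e-6)
  if (sum((q / axes)^2) >= 1)
    stop("point is not inside the ellipse/ellipsoid")
  f <- function(t) sum((axes * q / (axes^2 + t))^2) - 1
  lo <- -min(axes)^2
  root <- uniroot(f, lower = lo + 1e-9 * min(axes)^2, upper = 0,
                  tol = 1e-12)$root
  x <- axes^2 * q / (axes^2 + root)
  sqrt(sum((x - q)^2))
}

# Centres of the pixel grid along one axis: pixel i spans
# [(i-1)*h, i*h), centre (i-0.5)*h.
gridCentres <- function(n, h) (seq_len(n) - 0.5) * h
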