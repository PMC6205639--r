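# Shared fixtures built in code: a standard image-sized box and a small
# deterministic pattern for exact-geometry checks.

std_box <- function() bounding_box(640, 480)

# brute-force fraction of an M x M offset lattice for which a single point
# is counted; independent of the package's counting path
offset_sweep_fraction <- function(x, y, bbox, grid, M = 200) {
  th <- grid$theta * pi / 180
  qx <- cos(th) * (x - bbox$xmin) + sin(th) * (y - bbox$ymin)
  qy <- -sin(th) * (x - bbox$xmin) + cos(th) * (y - bbox$ymin)
  z <- (seq_len(M) - 0.5) * grid$period / M
  px <- ((qx - z) %% grid$period) < grid$t
  py <- ((qy - z) %% grid$period) < grid$t
  mean(px) * mean(py)
}
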