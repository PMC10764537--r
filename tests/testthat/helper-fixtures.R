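# Hand-constructed Y-shaped valley: two diagonal headwater channels joining
# a west-east trunk at (4, 5), everything else a flank sloping towards the
# nearest channel cell. With a flowline threshold of 6 m^2 the network is
# exactly: chain (2,3)-(3,4)-(4,5), chain (6,3)-(5,4)-(4,5), and trunk
# (4,5)-(4,9), the junction shared as a vertex.
y_valley_dem <- function() {
  nr <- 7; nc <- 9
  chan <- rbind(cbind(c(1, 2, 3), c(2, 3, 4)),
                cbind(c(7, 6, 5), c(2, 3, 4)),
                cbind(rep(4, 5), 5:9))
  zc <- c(10, 9, 8, 10, 9, 8, 7, 6, 5, 4, 3)
  z <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    d <- min(sqrt((chan[, 1] - r)^2 + (chan[, 2] - co)^2))
    z[r, co] <- 25 + 0.5 * d
  }
  z[chan] <- zc
  raster_grid(z, 1, units = "m elevation")
}

y_valley_threshold <- 6
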