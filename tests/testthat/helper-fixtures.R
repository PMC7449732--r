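# Small shared fixtures, built in code at load time.

lay1 <- arrayLayout(1, 1)           # single module
lay2 <- arrayLayout(1, 2)           # two modules side by side

# 8x8x8 toy grid spanning the two-module probe, with the wavelength pair
grid8 <- voxelGrid(c(8L, 8L, 8L), 5, origin = c(5, -5, 2.5))
j740.8 <- buildJacobian(lay2, grid8, wavelength = 740)
j855.8 <- buildJacobian(lay2, grid8, wavelength = 855)
msj8 <- multispectralJacobian(j740.8, j855.8)

# a ChannelSeries of synthetic intensities over the single-module channels
makeIntensitySeries <- function(values, layout = lay1, nt = ncol(values),
                                rate = 3) {
  ch <- enumerateChannels(layout, c(740, 855))
  stopifnot(nrow(values) == nrow(ch))
  channelSeries(list(intensity = values), ch,
                times = seq(0, by = 1 / rate, length.out = nt),
                metadata = list(layout = layout))
}

# a concentration-domain ChannelSeries over the single-module pairs
makeConcSeries <- function(hbo, hbr, layout = lay1, rate = 3) {
  ch <- enumerateChannels(layout, 740)
  ch$wavelength <- NULL
  stopifnot(nrow(hbo) == nrow(ch))
  channelSeries(list(HbO = hbo, HbR = hbr), ch,
                times = seq(0, by = 1 / rate, length.out = ncol(hbo)),
                metadata = list(layout = layout))
}

# independent semi-infinite Green's function (fresh code path, used as the
# oracle against greenCw / buildJacobian)
oracleGreen <- function(axy, b, props, wavelength) {
  p <- props[[as.character(wavelength)]]
  mut <- p$mua + p$musp
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * p$mua * mut)
  reff <- -1.440 / props$n^2 + 0.710 / props$n + 0.668 + 0.0636 * props$n
  zb <- 2 * D * (1 + reff) / (1 - reff)
  z0 <- 1 / p$musp
  r1 <- sqrt(sum((b - c(axy, z0))^2))
  r2 <- sqrt(sum((b - c(axy, -z0 - 2 * zb))^2))
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}
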