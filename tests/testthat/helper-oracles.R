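# Independent oracles used across the suite.  These deliberately avoid the
# package's trajectory/PA code paths: deflection angles come from the
# classical central-force deflection integral, shadow areas from dense grid
# quadrature, and speed averages from 1-D quadrature of the analytic
# Maxwell-Boltzmann weight.

KCAL_AKMA <- 4.184e-4   # kcal/mol -> Da A^2 / fs^2
KB_KCAL <- 0.0019872041

# deflection angle for a central potential V(r) at impact parameter b and
# collision energy E (kcal/mol), by quadrature of the deflection integral
# chi = pi - 2b * int_{r0}^inf dr / (r^2 sqrt(1 - b^2/r^2 - V/E))
chi_quadrature <- function(V, b, E, r_hi = 80) {
  f <- function(r) 1 - (b / r)^2 - V(r) / E
  r0 <- uniroot(f, c(1e-4, r_hi), tol = 1e-14)$root
  rr <- seq(r0 * 1.000001, r_hi, length.out = 800)
  fr <- f(rr)
  if (any(fr < 0)) { # pick the outermost turning point
    i <- max(which(fr < 0))
    r0 <- uniroot(f, c(rr[i], r_hi), tol = 1e-14)$root
  }
  integrand <- function(t) { # u = 1 - t^2 removes the sqrt singularity
    u <- 1 - t^2
    r <- r0 / u
    Fv <- 1 - (b * u / r0)^2 - V(r) / E
    2 * t / sqrt(pmax(Fv, 1e-30))
  }
  I <- integrate(integrand, 0, 1, rel.tol = 1e-8, subdivisions = 1000,
                 stop.on.error = FALSE)$value
  pi - 2 * (b / r0) * I
}

# momentum-transfer cross section Q(1)(E) = 2 pi int (1 - cos chi) b db
q1_quadrature <- function(V, E, b_hi, n_b = 160) {
  bs <- seq(1e-4, b_hi, length.out = n_b)
  ig <- vapply(bs, function(b) (1 - cos(chi_quadrature(V, b, E))) * b,
               numeric(1))
  2 * pi * pracma::trapz(bs, ig)
}

# temperature-averaged Omega(1,1) for a central potential: Gauss-Legendre
# in the reduced speed gamma with the analytic weight gamma^5 exp(-gamma^2)
omega11_quadrature <- function(V, mu, temperature, b_hi, n_gamma = 20,
                               gamma_range = c(0.05, 4.5)) {
  kT <- KB_KCAL * temperature
  gl <- pracma::gaussLegendre(n_gamma, gamma_range[1], gamma_range[2])
  w <- gl$w * gl$x^5 * exp(-gl$x^2)
  q <- vapply(gl$x, function(gam) q1_quadrature(V, kT * gam^2, b_hi),
              numeric(1))
  sum(w * q) / sum(w)
}

# dense-grid union area of discs with 2-D centres and radii
grid_shadow_area <- function(centers, radii, n_grid = 700) {
  xmin <- min(centers[, 1] - radii); xmax <- max(centers[, 1] + radii)
  ymin <- min(centers[, 2] - radii); ymax <- max(centers[, 2] + radii)
  xs <- seq(xmin, xmax, length.out = n_grid)
  ys <- seq(ymin, ymax, length.out = n_grid)
  inside <- matrix(FALSE, n_grid, n_grid)
  for (a in seq_len(nrow(centers)))
    inside <- inside | (outer(xs - centers[a, 1], ys - centers[a, 2],
                              function(dx, dy) dx^2 + dy^2) <= radii[a]^2)
  mean(inside) * (xmax - xmin) * (ymax - ymin)
}

# do two labelings describe the same partition (up to label names)?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# write an ensemble to xyzq files + manifest in a fresh directory
write_ensemble_fixture <- function(ens, dir = tempfile("ens")) {
  dir.create(dir)
  rows <- vapply(seq_along(ens$conformers), function(i) {
    f <- sprintf("conf_%03d.xyzq", i)
    write_xyzq(ens$conformers[[i]]$geometry, file.path(dir, f))
    sprintf("%s,%.6f,kcal/mol", f, ens$conformers[[i]]$energy)
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("file,energy,unit", rows), manifest)
  manifest
}

# hand-keyed copy of the packaged reference tables (transcribed
# independently of inst/extdata/reference_ccs.csv) for checksum tests
ref_hand <- list(
  peptide = c("ANELLINVK","AWEVTVK","AWSVAR","DYYFALAHTVR","ELR","EWTR",
              "EYK","FAAYLER","FLNR","FPK","FSSDR","GLVK","LWSAK","NFNR",
              "NIATGSK","poly-6-glycine","poly-8-glycine","poly-10-glycine",
              "poly-14-glycine","TFAEALR","TIAQYAR","VASLR","WIR"),
  exp  = c(322.50,278.20,255.70,374.80,200.30,229.70,203.20,293.10,231.60,
           184.70,234.50,205.30,237.70,224.00,255.30,171.04,206.52,216.15,
           254.51,281.80,280.00,232.00,213.20),
  b3   = c(347.62,333.91,290.00,410.42,197.81,250.20,213.81,335.07,250.13,
           193.09,250.05,210.80,267.85,252.51,298.74,176.67,203.34,232.7,
           277.82,339.29,315.95,230.65,210.41),
  d30  = c(322.93,295.78,264.29,412.60,203.43,241.93,210.64,302.10,231.08,
           188.53,250.86,210.69,243.40,247.61,257.95,174.29,201.43,222.58,
           266.42,304.43,282.10,223.39,217.68),
  dbj  = c(342.93,296.11,274.98,422.64,201.62,243.40,209.78,307.17,238.48,
           188.59,240.25,210.63,243.63,239.92,248.67,170.03,197.56,222.02,
           266.33,295.93,300.94,232.05,208.50),
  d30p = c(335.91,286.04,274.57,389.49,207.93,237.44,209.74,292.77,237.89,
           188.09,241.62,208.71,236.19,219.20,260.08,172.39,197.76,225.89,
           264.76,295.01,280.33,228.70,205.63),
  dbjp = c(332.21,294.42,265.11,392.12,199.88,237.03,209.02,287.53,237.60,
           187.84,241.31,211.01,250.71,217.09,253.95,175.29,197.50,219.44,
           263.74,290.69,277.79,228.30,210.41)
)
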