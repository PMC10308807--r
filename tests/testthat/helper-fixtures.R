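# shared fixtures for the suite
water <- fluid_properties(997, 0.072)
bacterial <- fluid_properties(1200, 0.069, power_law_K = 0.05,
                              power_law_n = 0.4)

# zero-gravity spherical-cap closed forms, independent of the package
# internals: V = (pi h^2 / 3)(3R - h), h = R (1 - cos theta),
# a = R sin theta, with R the sphere radius (= 1/b)
cap_oracle <- function(R_m, theta_deg) {
  th <- theta_deg * pi / 180
  h <- R_m * (1 - cos(th))
  list(volume_uL = pi * h^2 / 3 * (3 * R_m - h) * 1e9,
       radius_mm = R_m * sin(th) * 1e3,
       height_mm = h * 1e3)
}

# analytic asymmetric profile: two circular-arc flanks of common
# height h_mm meeting at the apex, contact angles thetaL / thetaR
asym_cap_profile <- function(thetaL, thetaR, h_mm = 1, n = 400) {
  arc <- function(theta) {
    R <- h_mm / (1 - cos(theta * pi / 180))
    z <- seq(0, h_mm, length.out = n)
    # inward horizontal distance from the contact point, at height z
    x0 <- sqrt(R^2 - (R - h_mm)^2)
    list(z = z, inward = x0 - sqrt(pmax(R^2 - (R - h_mm + z)^2, 0)))
  }
  la <- arc(thetaL); ra <- arc(thetaR)
  wl <- max(la$inward); wr <- max(ra$inward)
  r_left <- la$inward
  r_right <- wl + rev(wr - ra$inward)
  drop_profile(c(r_left, r_right[-1]),
               c(la$z, rev(ra$z)[-1]),
               pixel_scale = 0.01)
}
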