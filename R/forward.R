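#' Three-shell spherical head model
#'
#' Concentric brain/skull/scalp conductor geometry. The default skull
#' conductivity honours the classical 1/80 brain-to-skull conductivity
#' ratio (0.33 / 80 = 0.004125 S/m); the historically printed rounded value
#' 0.042 S/m can be selected by passing it explicitly.
#'
#' @param radii_m Increasing radii (m) of the brain, skull and scalp shells.
#' @param conductivities_sm Conductivities (S/m) of brain, skull, scalp.
#' @return An object of class `shell_model`.
#' @export
shell_model <- function(radii_m = c(0.087, 0.092, 0.100),
                        conductivities_sm = c(0.33, 0.33 / 80, 0.33)) {
  if (length(radii_m) != 3 || any(diff(radii_m) <= 0) || any(radii_m <= 0)) {
    stop_assrmix("`radii_m` must be three increasing positive radii (brain < skull < scalp).")
  }
  if (length(conductivities_sm) != 3 || any(conductivities_sm <= 0)) {
    stop_assrmix("`conductivities_sm` must be three positive values.")
  }
  structure(list(radii_m = radii_m, conductivities_sm = conductivities_sm),
            class = "shell_model")
}

#' Current dipole inside the brain shell
#'
#' @param position_m Cartesian position (head-centred RAS, metres): x right,
#'   y anterior, z superior. Must lie strictly inside the brain shell.
#' @param orientation Direction of the dipole moment; normalised internally.
#' @param role One of `"cochlea"`, `"brainstem"`, `"thalamus_l"`,
#'   `"thalamus_r"`, `"a1_l"`, `"a1_r"`.
#' @return An object of class `dipole`.
#' @export
dipole <- function(position_m, orientation, role) {
  role <- match.arg(role, c("cochlea", "brainstem", "thalamus_l",
                            "thalamus_r", "a1_l", "a1_r"))
  position_m <- as.numeric(position_m)
  orientation <- as.numeric(orientation)
  if (length(position_m) != 3 || length(orientation) != 3) {
    stop_assrmix("`position_m` and `orientation` must be length-3 vectors.")
  }
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop_assrmix("`orientation` must be non-zero.")
  structure(list(position_m = position_m, orientation = orientation / nrm,
                 role = role),
            class = "dipole")
}

#' Default six-dipole set
#'
#' Bundled synthetic dipole coordinates and orientations: a cochlear
#' (artifactual) dipole in the temporal-bone region on the implant side
#' with a radial orientation (ipsilateral artifact spread), a midline
#' brainstem dipole and bilateral thalamic/cortical dipoles oriented toward
#' the vertex so the ASSR topography focalises over the fronto-central
#' electrodes. These are plausibility-tuned stand-ins, not subject-derived
#' coordinates.
#'
#' @param implant_side `"right"` (default) or `"left"`.
#' @return A named list of six [dipole()] objects in canonical order
#'   (`brainstem`, `thalamus_l`, `thalamus_r`, `a1_l`, `a1_r`, `cochlea`).
#' @export
default_dipoles <- function(implant_side = c("right", "left")) {
  implant_side <- match.arg(implant_side)
  sgn <- if (implant_side == "right") 1 else -1
  coch_pos <- c(sgn * 0.072, 0.005, -0.030)
  list(
    brainstem  = dipole(c(0, -0.025, -0.030), c(0, 0.35, 0.94), "brainstem"),
    thalamus_l = dipole(c(-0.011, -0.018, 0.005), c(0, 0.1, 1), "thalamus_l"),
    thalamus_r = dipole(c(0.011, -0.018, 0.005), c(0, 0.1, 1), "thalamus_r"),
    a1_l = dipole(c(-0.052, -0.019, 0.012), c(0, 0.2, 1), "a1_l"),
    a1_r = dipole(c(0.052, -0.019, 0.012), c(0, 0.2, 1), "a1_r"),
    cochlea = dipole(coch_pos, coch_pos, "cochlea")
  )
}

#' 32-channel 10-10 electrode montage
#'
#' Standard 32-electrode subset of the 10-10 system on the spherical scalp,
#' constructed geometrically: midline and circumferential-ring electrodes at
#' their canonical inclination/azimuth, intermediate electrodes as
#' great-circle midpoints. Exactly left/right symmetric.
#'
#' @param scalp_radius_m Scalp sphere radius (m).
#' @return An object of class `montage`: a tibble with columns `label`,
#'   `x`, `y`, `z` (metres, head-centred RAS) and attribute
#'   `scalp_radius_m`.
#' @export
montage_10_10_32 <- function(scalp_radius_m = 0.100) {
  check_scalar(scalp_radius_m, "scalp_radius_m")
  ia <- function(incl, az) { # unit vector from inclination/azimuth (degrees)
    i <- incl * pi / 180
    a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  slerp_mid <- function(u, v) { w <- u + v; w / sqrt(sum(w^2)) }
  base <- list(
    Fp1 = ia(72, -18), Fp2 = ia(72, 18), F7 = ia(72, -54), F8 = ia(72, 54),
    T7 = ia(72, -90), T8 = ia(72, 90), P7 = ia(72, -126), P8 = ia(72, 126),
    O1 = ia(72, -162), O2 = ia(72, 162), Oz = ia(72, 180),
    Fz = ia(36, 0), Cz = ia(0, 0), Pz = ia(36, 180),
    C3 = ia(36, -90), C4 = ia(36, 90),
    TP9 = ia(108, -108), TP10 = ia(108, 108),
    PO9 = ia(108, -144), PO10 = ia(108, 144)
  )
  base$F3 <- slerp_mid(base$Fz, base$F7); base$F4 <- slerp_mid(base$Fz, base$F8)
  base$P3 <- slerp_mid(base$Pz, base$P7); base$P4 <- slerp_mid(base$Pz, base$P8)
  base$FC5 <- slerp_mid(base$F7, base$C3); base$FC6 <- slerp_mid(base$F8, base$C4)
  base$FC1 <- slerp_mid(base$Fz, base$C3); base$FC2 <- slerp_mid(base$Fz, base$C4)
  base$CP5 <- slerp_mid(base$P7, base$C3); base$CP6 <- slerp_mid(base$P8, base$C4)
  base$CP1 <- slerp_mid(base$Pz, base$C3); base$CP2 <- slerp_mid(base$Pz, base$C4)
  order <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
             "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
             "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz",
             "O2", "PO10")
  pos <- unname(do.call(rbind, base[order])) * scalp_radius_m
  out <- tibble::tibble(label = order, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  structure(out, scalp_radius_m = scalp_radius_m,
            class = c("montage", class(out)))
}

# ---- analytic concentric-sphere lead field ---------------------------------

# internal: per-harmonic surface transfer factors tau_n for the 3-shell
# model, for a dipole at normalized eccentricity f = b / r_scalp.
# tau_n multiplies [n m_r P_n + m_t P_n^1 cos(phi)] and already includes the
# f^(n-1) eccentricity factor; the caller scales by 1/(4 pi sigma_brain R^2).
shell_transfer <- function(f, shells, n_max) {
  rr <- shells$radii_m / shells$radii_m[3] # normalized radii: r1, r2, 1
  s <- shells$conductivities_sm
  n <- seq_len(n_max)
  tau <- numeric(n_max)
  r1 <- rr[1]; r2 <- rr[2]
  for (k in n) {
    cn <- f^(k - 1) # source coefficient (normalized units)
    if (cn < 1e-280) break # remaining taus stay zero
    # unknowns: A1, A2, B2, A3, B3
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # continuity of V at r1
    M[1, ] <- c(r1^k, -r1^k, -r1^(-(k + 1)), 0, 0)
    rhs[1] <- -cn * r1^(-(k + 1))
    # continuity of sigma dV/dr at r1
    M[2, ] <- c(s[1] * k * r1^(k - 1), -s[2] * k * r1^(k - 1),
                s[2] * (k + 1) * r1^(-(k + 2)), 0, 0)
    rhs[2] <- s[1] * (k + 1) * cn * r1^(-(k + 2))
    # continuity of V at r2
    M[3, ] <- c(0, r2^k, r2^(-(k + 1)), -r2^k, -r2^(-(k + 1)))
    # continuity of sigma dV/dr at r2
    M[4, ] <- c(0, s[2] * k * r2^(k - 1), -s[2] * (k + 1) * r2^(-(k + 2)),
                -s[3] * k * r2^(k - 1), s[3] * (k + 1) * r2^(-(k + 2)))
    # insulating outer boundary at r = 1
    M[5, ] <- c(0, 0, 0, k, -(k + 1))
    # row/column equilibration: entries span ~r1^(+-k), ill-conditioned raw
    dr <- apply(abs(M), 1, max)
    M <- M / dr
    rhs <- rhs / dr
    dc <- apply(abs(M), 2, max)
    M <- sweep(M, 2, dc, "/")
    sol <- solve(M, rhs) / dc
    tau[k] <- sol[4] + sol[5] # A3 + B3 at r = 1
  }
  tau
}

#' Analytic three-shell sphere lead field
#'
#' Quasi-static potential per unit dipole moment at each electrode for the
#' concentric three-sphere head model, by the standard spherical-harmonic
#' series: per harmonic the radial two-point boundary problem is solved
#' exactly, and the series is truncated once terms fall below `tol`
#' relative to the accumulated sum (hard cap `n_max`). Dipole orientations
#' are folded in, giving fixed-orientation columns.
#'
#' @param dipoles List of [dipole()] objects.
#' @param montage A [montage_10_10_32()] (or compatible tibble with
#'   `label`, `x`, `y`, `z` on the scalp sphere).
#' @param shells A [shell_model()].
#' @param n_max Maximum spherical-harmonic degree.
#' @param tol Relative truncation tolerance.
#' @return An object of class `lead_field`: an `n_electrodes x n_dipoles`
#'   matrix (V per A·m, i.e. potential per unit dipole moment) with
#'   dimnames (electrode labels, dipole roles) and attributes `provenance`
#'   (`"analytic-sphere"`), `labels`, `roles`.
#' @export
sphere_lead_field <- function(dipoles, montage = montage_10_10_32(),
                              shells = shell_model(), n_max = 400L,
                              tol = 1e-12) {
  stopifnot(inherits(shells, "shell_model"))
  if (inherits(dipoles, "dipole")) dipoles <- list(dipoles)
  r3 <- shells$radii_m[3]
  elec <- as.matrix(montage[, c("x", "y", "z")])
  if (max(abs(sqrt(rowSums(elec^2)) - r3)) > 1e-6 * r3) {
    stop_assrmix("Electrode positions must lie on the scalp sphere radius.")
  }
  lf <- matrix(0, nrow(elec), length(dipoles))
  for (d in seq_along(dipoles)) {
    dp <- dipoles[[d]]
    stopifnot(inherits(dp, "dipole"))
    b <- sqrt(sum(dp$position_m^2))
    if (b >= shells$radii_m[1]) {
      stop_assrmix(sprintf("Dipole `%s` lies outside the brain shell.", dp$role))
    }
    if (b < 1e-12) {
      ez <- dp$orientation
      m_r <- 1; m_t <- 0
      ex <- c(0, 0, 0)
    } else {
      ez <- dp$position_m / b
      m_r <- sum(dp$orientation * ez)
      tvec <- dp$orientation - m_r * ez
      m_t <- sqrt(sum(tvec^2))
      ex <- if (m_t > 1e-12) tvec / m_t else c(0, 0, 0)
    }
    f <- b / r3
    tau <- shell_transfer(f, shells, n_max)
    # electrode angles
    u <- elec / r3
    ct <- pmin(1, pmax(-1, as.numeric(u %*% ez))) # cos(gamma)
    st <- sqrt(pmax(0, 1 - ct^2))
    cp <- as.numeric(u %*% ex)                    # sin(gamma) cos(phi)
    # P_n(cos) and P_n^1(cos) by upward recurrence (P_n^1 = s * dP_n/dx)
    v <- numeric(nrow(elec))
    Pm2 <- rep(1, nrow(elec)); Pm1 <- as.numeric(ct)          # P0, P1
    Qm2 <- rep(0, nrow(elec)); Qm1 <- st                      # P0^1, P1^1
    scalemax <- 0
    for (k in seq_len(n_max)) {
      Pk <- if (k == 1) Pm1 else ((2 * k - 1) * ct * Pm1 - (k - 1) * Pm2) / k
      Qk <- if (k == 1) {
        Qm1
      } else {
        ((2 * k - 1) * ct * Qm1 - k * Qm2) / (k - 1)
      }
      # note: cp already contains sin(gamma) * cos(phi); P_n^1 = s dP/dx,
      # so the tangential angular factor is (Q_k / s) * s * cos(phi) = Q_k
      # rebuilt from cp: Q_k * cos(phi) = (Q_k / st) * cp where defined.
      ang_t <- ifelse(st > 1e-14, Qk / st, 0) * cp
      term <- tau[k] * (k * m_r * Pk + m_t * ang_t)
      v <- v + term
      scalemax <- max(scalemax, max(abs(term)))
      if (k > 10 && max(abs(term)) < tol * max(scalemax, .Machine$double.eps)) {
        break
      }
      if (k == n_max && max(abs(term)) > 1e-6 * scalemax) {
        stop_assrmix("Lead-field series did not converge; increase `n_max`.")
      }
      if (k > 1) { Pm2 <- Pm1; Pm1 <- Pk; Qm2 <- Qm1; Qm1 <- Qk }
    }
    lf[, d] <- v / (4 * pi * shells$conductivities_sm[1] * r3^2)
  }
  dimnames(lf) <- list(montage$label,
                       unname(vapply(dipoles, `[[`, character(1), "role")))
  structure(lf, provenance = "analytic-sphere", labels = montage$label,
            roles = colnames(lf), class = c("lead_field", "matrix", "array"))
}
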