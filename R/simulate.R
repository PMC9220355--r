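#' Seeded synthetic-data generators
#'
#' Every generator takes an integer `seed` and a scenario name internally
#' derives an independent substream seed from both, so the same global
#' seed always reproduces the same fixture bit-for-bit and adding a new
#' generator never perturbs existing ones. Each generator returns its
#' ground truth alongside the data.
#'
#' @name synthetic-data
NULL

# named-stream splitter: deterministic substream seed from (seed, name)
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1048573 + h) %% 2147483629)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(expr)
}

#' Generate a species energy table with known decomposition
#'
#' Draws the physical components (interaction, deformations, dehydration,
#' counterpoise parts, thermal corrections) from stated uniform ranges —
#' or takes them verbatim from `components` — and constructs species
#' electronic energies consistent with both assembly routes of the
#' thermodynamic cycle. The bare active site's native energy is emitted as
#' a shared `"*"` block.
#'
#' @param seed Integer seed.
#' @param n_ligands Number of ligands (ignored when `components` given).
#' @param ranges Named list of `c(lo, hi)` component ranges in kJ/mol:
#'   `int`, `def_A`, `def_L`, `dehydr`, `bsse_A`, `bsse_L`, `g_corr`
#'   (the net thermal correction to binding).
#' @param components Optional data frame `ligand_id, dE_int, dE_def_A,
#'   dE_def_L, dE_dehydr_L, dE_bsse_A, dE_bsse_L` (optional
#'   `dG_bind_corr`) fixing the decomposition exactly.
#' @return List: `records` ([energy_table()]), `thermal`
#'   (thermal-correction table), `truth` (the implied decomposition, one
#'   row per ligand with `dE_bind`, `dG_bind_corr`, `dG_bind`).
#' @export
gen_energy_table <- function(seed, n_ligands = 8,
                             ranges = list(int = c(-320, -60),
                                           def_A = c(0, 30),
                                           def_L = c(0, 30),
                                           dehydr = c(0, 90),
                                           bsse_A = c(-15, 0),
                                           bsse_L = c(-15, 0),
                                           g_corr = c(10, 70)),
                             components = NULL) {
  with_stream(seed, "energy_table", {
    if (is.null(components)) {
      u <- function(nm, n) stats::runif(n, ranges[[nm]][1], ranges[[nm]][2])
      components <- data.frame(
        ligand_id = sprintf("lig%02d", seq_len(n_ligands)),
        dE_int = u("int", n_ligands),
        dE_def_A = u("def_A", n_ligands),
        dE_def_L = u("def_L", n_ligands),
        dE_dehydr_L = u("dehydr", n_ligands),
        dE_bsse_A = u("bsse_A", n_ligands),
        dE_bsse_L = u("bsse_L", n_ligands),
        dG_bind_corr = u("g_corr", n_ligands),
        stringsAsFactors = FALSE)
    } else {
      components <- as.data.frame(components)
      if (is.null(components$dG_bind_corr))
        components$dG_bind_corr <- stats::runif(
          nrow(components), ranges$g_corr[1], ranges$g_corr[2])
      n_ligands <- nrow(components)
    }

    E_A_nat <- stats::runif(1, -3e6, -2e6)
    g_A <- stats::runif(1, 200, 400)
    rec <- list(data.frame(ligand_id = "*", species = "A",
                           geometry = "native", basis = "own",
                           solvent = "DEE", energy = E_A_nat,
                           stringsAsFactors = FALSE))
    th <- list(data.frame(ligand_id = "*", species = "A", g_corr = g_A,
                          stringsAsFactors = FALSE))
    truth <- components
    truth$dE_bsse <- truth$dE_bsse_A + truth$dE_bsse_L
    truth$dE_bind <- truth$dE_int + truth$dE_def_A + truth$dE_def_L +
      truth$dE_dehydr_L + truth$dE_bsse
    truth$dG_bind <- truth$dE_bind + truth$dG_bind_corr

    for (i in seq_len(n_ligands)) {
      cm <- components[i, ]
      lid <- cm$ligand_id
      E_L_w <- stats::runif(1, -8e5, -2e5)
      E_L_d <- E_L_w + cm$dE_dehydr_L
      E_L_c <- E_L_d + cm$dE_def_L
      E_A_c <- E_A_nat + cm$dE_def_A
      E_AL  <- cm$dE_int + E_A_c + E_L_c
      row <- function(species, geometry, basis, solvent, energy)
        data.frame(ligand_id = lid, species = species, geometry = geometry,
                   basis = basis, solvent = solvent, energy = energy,
                   stringsAsFactors = FALSE)
      rec[[length(rec) + 1L]] <- do.call(rbind, list(
        row("AL", "native",  "own",     "DEE",   E_AL),
        row("L",  "native",  "own",     "water", E_L_w),
        row("L",  "native",  "own",     "DEE",   E_L_d),
        row("L",  "complex", "own",     "DEE",   E_L_c),
        row("A",  "complex", "own",     "DEE",   E_A_c),
        row("A",  "complex", "complex", "DEE",   E_A_c + cm$dE_bsse_A),
        row("L",  "complex", "complex", "DEE",   E_L_c + cm$dE_bsse_L)))
      g_L <- stats::runif(1, 50, 200)
      g_AL <- cm$dG_bind_corr + g_A + g_L
      th[[length(th) + 1L]] <- data.frame(
        ligand_id = lid, species = c("L", "AL"), g_corr = c(g_L, g_AL),
        stringsAsFactors = FALSE)
    }
    list(records = energy_table(do.call(rbind, rec)),
         thermal = thermal_table(do.call(rbind, th)),
         truth = truth)
  })
}

#' Generate a copper-site hydration trajectory
#'
#' Emulates the solvated active site: the copper fixed at the box center,
#' per-shell water oxygens placed at radius ~ Normal(radius, sigma) in a
#' uniformly random direction with the stated per-frame occupancy, and the
#' remaining waters uniform in the periodic box (wrapped each frame).
#' Hydrogens are not generated; the hydration analysis counts oxygens.
#'
#' @param seed Integer seed.
#' @param n_frames Number of frames.
#' @param shells Data frame `radius, sigma, occupancy` (Angstrom, Angstrom,
#'   waters per frame); default the two observed shells at 2.5 / 3.2
#'   Angstrom, sigma 0.1, one water each.
#' @param n_bulk Bulk waters uniform in the box.
#' @param box Orthorhombic box lengths, Angstrom.
#' @param r_exclude Excluded-volume radius around the copper, Angstrom:
#'   bulk waters are resampled until outside it (minimum-image distance),
#'   mimicking the fact that solvent cannot overlap the ion. Set to 0 for
#'   a strictly homogeneous (ideal-gas) fixture.
#' @return A [traj_frames()] object; the generator spec is attached as
#'   attribute `truth` (shell table, box, counts). A warning flag
#'   `overlapping_shells` is attached when adjacent shells overlap within
#'   one joint standard deviation.
#' @export
gen_site_trajectory <- function(seed, n_frames = 500,
                                shells = data.frame(radius = c(2.5, 3.2),
                                                    sigma = c(0.1, 0.1),
                                                    occupancy = c(1, 1)),
                                n_bulk = 200, box = c(18.6, 18.6, 18.6),
                                r_exclude = 2) {
  shells <- as.data.frame(shells)
  if (nrow(shells) && any(shells$radius >= min(box) / 2))
    stop("shell radii must be smaller than half the box")
  overlap <- FALSE
  if (nrow(shells) > 1L) {
    o <- order(shells$radius)
    rr <- shells$radius[o]; ss <- shells$sigma[o]
    gap <- diff(rr)
    if (any(gap < (ss[-length(ss)] + ss[-1]))) {
      overlap <- TRUE
      warning("overlapping hydration shells in generator spec")
    }
  }
  with_stream(seed, "site_trajectory", {
    center <- box / 2
    n_shell <- if (nrow(shells)) sum(shells$occupancy) else 0L
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      pts <- matrix(center, nrow = 1)
      for (s in seq_len(nrow(shells))) {
        for (w in seq_len(shells$occupancy[s])) {
          v <- stats::rnorm(3)
          v <- v / sqrt(sum(v^2))
          rad <- if (shells$sigma[s] > 0)
            stats::rnorm(1, shells$radius[s], shells$sigma[s])
          else shells$radius[s]
          pts <- rbind(pts, center + abs(rad) * v)
        }
      }
      if (n_bulk > 0) {
        bulk <- matrix(NA_real_, 0, 3)
        while (nrow(bulk) < n_bulk) {
          cand <- cbind(stats::runif(n_bulk, 0, box[1]),
                        stats::runif(n_bulk, 0, box[2]),
                        stats::runif(n_bulk, 0, box[3]))
          if (r_exclude > 0) {
            d <- sweep(cand, 2, center)
            for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
            cand <- cand[rowSums(d * d) > r_exclude^2, , drop = FALSE]
          }
          bulk <- rbind(bulk, cand)
        }
        pts <- rbind(pts, bulk[seq_len(n_bulk), , drop = FALSE])
      }
      # wrap into the box
      for (k in 1:3) pts[, k] <- pts[, k] %% box[k]
      frames[[f]] <- unname(pts)
    }
    element <- c("Cu", rep("O", n_shell + n_bulk))
    tr <- traj_frames(frames, element, box = box)
    # expected location of the g(r) maximum for each shell: with radius
    # ~ Normal(mu, sigma), g ~ exp(-(r-mu)^2/(2 sigma^2)) / r^2 peaks at
    # (mu + sqrt(mu^2 - 8 sigma^2))/2, slightly inside mu
    g_peak <- if (nrow(shells))
      (shells$radius + sqrt(pmax(shells$radius^2 - 8 * shells$sigma^2, 0))) / 2
    else numeric(0)
    attr(tr, "truth") <- list(shells = shells, g_peak = g_peak,
                              n_bulk = n_bulk, box = box,
                              overlapping_shells = overlap, seed = seed)
    tr
  })
}

#' Generate an idealized copper-site geometry from a distance row
#'
#' Places the six donors along idealized octahedral axes at the stated
#' Cu-donor distances: the three brace nitrogens and `L_eq` in the
#' equatorial plane at 90-degree spacing, `O_Tyr166` and `L_ax` on the
#' +z/-z axes. Bond angles are idealized; only distances are meaningful.
#' `NA` distances leave the position unoccupied.
#'
#' @param distances Named numeric vector (names in [SITE_ROLES]) or
#'   unnamed length-6 vector in that order, Angstrom.
#' @param cu Cu position (default origin).
#' @return A [site_model()]; intended axial/equatorial roles are attached
#'   as attribute `truth`.
#' @export
gen_site_geometry <- function(distances, cu = c(0, 0, 0)) {
  if (is.null(names(distances))) {
    if (length(distances) != 6L) stop("need 6 distances or a named vector")
    names(distances) <- SITE_ROLES
  }
  bad <- setdiff(names(distances), SITE_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (any(!is.na(distances) & distances <= 0))
    stop("distances must be positive")
  axes <- rbind(N_im_MeHis1 = c(1, 0, 0),
                N_am_MeHis1 = c(0, 1, 0),
                N_im_His83 = c(-1, 0, 0),
                O_Tyr166 = c(0, 0, 1),
                L_eq = c(0, -1, 0),
                L_ax = c(0, 0, -1))
  keep <- names(distances)[!is.na(distances)]
  donors <- do.call(rbind, lapply(keep, function(role) {
    p <- cu + distances[[role]] * axes[role, ]
    data.frame(role = role, x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  }))
  sm <- site_model(cu, donors)
  attr(sm, "truth") <- list(
    distances = distances,
    roles = c(O_Tyr166 = "axial", L_eq = "equatorial", L_ax = "axial"))
  sm
}

#' Generate noisy exponential dose-response series
#'
#' `A(c) = A0 * exp(-ln(2) * c / ic50) * (1 + eps)`,
#' `eps ~ Normal(0, noise)` (multiplicative noise; draws are truncated at
#' -0.99 so activities stay positive).
#'
#' @param seed Integer seed.
#' @param n_series Number of independent series.
#' @param A0 Zero-dose activity.
#' @param ic50 True IC50, mM.
#' @param noise Relative noise SD (0 for noiseless).
#' @param concentrations Inhibitor concentrations, mM.
#' @return Data frame `series, concentration_mM, activity` with the truth
#'   (`A0`, `ic50`, `k`) as attribute `truth`.
#' @export
gen_dose_response <- function(seed, n_series = 1, A0 = 100, ic50 = 1,
                              noise = 0.05,
                              concentrations = c(0, 0.25, 0.5, 1, 2, 4, 6, 8)) {
  k <- log(2) / ic50
  with_stream(seed, "dose_response", {
    out <- do.call(rbind, lapply(seq_len(n_series), function(s) {
      mu <- A0 * exp(-k * concentrations)
      eps <- if (noise > 0) pmax(stats::rnorm(length(mu), 0, noise), -0.99)
             else 0
      data.frame(series = s, concentration_mM = concentrations,
                 activity = mu * (1 + eps))
    }))
    attr(out, "truth") <- list(A0 = A0, ic50 = ic50, k = k, noise = noise)
    out
  })
}

#' Generate linear ln(IC50) vs binding-energy datasets
#'
#' Draws binding energies uniformly over `dg_range` and sets
#' `ln(IC50) = a + b * dG + Normal(0, sigma)`.
#'
#' @param seed Integer seed.
#' @param n Points per dataset.
#' @param n_sets Number of replicate datasets drawn from the one stream.
#' @param a Intercept, ln(mM).
#' @param b Slope, per kJ/mol.
#' @param sigma Residual SD of ln(IC50).
#' @param dg_range Range of binding energies, kJ/mol.
#' @return Data frame `set, dG_bind, ic50_mM` with truth attached as
#'   attribute `truth`.
#' @export
gen_correlation <- function(seed, n = 11, n_sets = 1, a = 1, b = 0.04,
                            sigma = 0.3, dg_range = c(-270, -50)) {
  with_stream(seed, "correlation", {
    out <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
      dg <- stats::runif(n, dg_range[1], dg_range[2])
      lni <- a + b * dg + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
      data.frame(set = s, dG_bind = dg, ic50_mM = exp(lni))
    }))
    attr(out, "truth") <- list(a = a, b = b, sigma = sigma)
    out
  })
}
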