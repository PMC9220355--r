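# Independent oracle implementations used to cross-check the package's
# numerics. These deliberately take different algorithmic routes than the
# implementations under test.

# Horn's quaternion method for optimal superposition: the minimal RMSD
# follows from the largest eigenvalue of the 4x4 quaternion matrix, with
# no SVD involved.
quaternion_rmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# literal greedy neighbor-count clustering, recomputing neighbor counts
# from the full matrix at every step
greedy_cluster_oracle <- function(rmsd, cutoff) {
  remaining <- seq_len(nrow(rmsd))
  clusters <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(rmsd[i, remaining] <= cutoff), 0L)
    centroid <- remaining[which.max(counts)]
    members <- remaining[rmsd[centroid, remaining] <= cutoff]
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid,
                                              members = members)
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  cents <- vapply(clusters, function(cl) cl$centroid, 0L)
  clusters[order(-sizes, cents)]
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a*a+b*b-c*c-d*d, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a*a-b*b+c*c-d*d, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a*a-b*b-c*c+d*d),
         3, 3, byrow = TRUE)
}

# apply a rigid-body transform to every coordinate a site model carries
transform_site <- function(site, R, t) {
  tp <- function(m) sweep(as.matrix(m) %*% R, 2, t, `+`)
  cu <- as.numeric(tp(matrix(site$cu, 1)))
  donors <- site$donors
  donors[c("x", "y", "z")] <- tp(donors[c("x", "y", "z")])
  la <- site$ligand_atoms
  if (!is.null(la)) la[c("x", "y", "z")] <- tp(la[c("x", "y", "z")])
  hy <- site$hydrogens
  if (!is.null(hy)) hy[c("x", "y", "z")] <- tp(hy[c("x", "y", "z")])
  ring <- site$ring
  if (!is.null(ring)) ring <- lapply(ring, tp)
  site_model(cu, donors, ligand_atoms = la, hydrogens = hy, ring = ring)
}

# minimal energy table realizing given species energies for one ligand
make_energy_records <- function(ligand = "lig",
                                E_AL, E_A, E_L_w, E_L_d = E_L_w,
                                E_A_c = E_A, E_L_c = E_L_d,
                                bsse_A = 0, bsse_L = 0) {
  row <- function(species, geometry, basis, solvent, energy)
    data.frame(ligand_id = ligand, species = species, geometry = geometry,
               basis = basis, solvent = solvent, energy = energy,
               stringsAsFactors = FALSE)
  energy_table(rbind(
    row("AL", "native",  "own",     "DEE",   E_AL),
    row("A",  "native",  "own",     "DEE",   E_A),
    row("L",  "native",  "own",     "water", E_L_w),
    row("L",  "native",  "own",     "DEE",   E_L_d),
    row("A",  "complex", "own",     "DEE",   E_A_c),
    row("L",  "complex", "own",     "DEE",   E_L_c),
    row("A",  "complex", "complex", "DEE",   E_A_c + bsse_A),
    row("L",  "complex", "complex", "DEE",   E_L_c + bsse_L)))
}

# hand-built rdf_profile for shell-finding tests
fake_profile <- function(r, g, density = 0.0334) {
  structure(list(r = r, g = g, counts = g, dr = r[2] - r[1],
                 r_max = max(r) + (r[2] - r[1]) / 2, density = density,
                 n_frames = 1L, n_target = 1L,
                 ref = "copper", target = "water_oxygen"),
            class = "rdf_profile")
}
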