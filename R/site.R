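#' Copper-site model
#'
#' A labeled model of the Cu(II) coordination environment: the copper
#' position, the protein donor atoms of the histidine brace and axial
#' tyrosine, the exchangeable equatorial/axial positions (`L_eq`, `L_ax`,
#' occupied by water or an inhibitor donor atom), optional extra ligand
#' atoms (with donor flags for denticity counting) and optional polar
#' hydrogens for hydrogen-bond scoring.
#'
#' Donor roles, in the fixed reporting order:
#' `N_im_MeHis1` (imidazole N of the methylated N-terminal histidine),
#' `N_am_MeHis1` (its terminal amine N), `N_im_His83`, `O_Tyr166`,
#' `L_eq`, `L_ax`.
#'
#' @param cu Numeric length-3 Cu position, Angstrom.
#' @param donors Data frame with columns `role`, `x`, `y`, `z`. Roles must
#'   be unique; any subset of the six standard roles (absent roles are
#'   reported as unoccupied).
#' @param ligand_atoms Optional data frame `name`, `element`, `is_donor`,
#'   `x`, `y`, `z` for the bound small molecule.
#' @param hydrogens Optional data frame `name`, `partner` (name or role of
#'   the covalently bound heavy atom), `x`, `y`, `z` of polar hydrogens.
#' @param ring Optional named list: role -> m x 3 matrix of aromatic ring
#'   carbon coordinates, for pi-coordinated positions reported as the mean
#'   Cu-carbon distance.
#' @return Object of class `site_model`.
#' @export
site_model <- function(cu, donors, ligand_atoms = NULL, hydrogens = NULL,
                       ring = NULL) {
  cu <- as.numeric(cu)
  if (length(cu) != 3L || !all(is.finite(cu))) stop("cu must be a finite xyz triple")
  donors <- as.data.frame(donors)
  need <- c("role", "x", "y", "z")
  if (!all(need %in% names(donors))) stop("donors need columns role, x, y, z")
  if (anyDuplicated(donors$role)) stop("duplicate donor roles")
  bad <- setdiff(donors$role, SITE_ROLES)
  if (length(bad)) stop("unknown donor role(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(donors[c("x", "y", "z")]))))
    stop("non-finite donor coordinates")
  structure(list(cu = cu, donors = donors, ligand_atoms = ligand_atoms,
                 hydrogens = hydrogens, ring = ring),
            class = "site_model")
}

#' @rdname site_model
#' @format NULL
#' @export
SITE_ROLES <- c("N_im_MeHis1", "N_am_MeHis1", "N_im_His83",
                "O_Tyr166", "L_eq", "L_ax")

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Cu-donor distance table
#'
#' Euclidean Cu-donor distances in the fixed six-role order, reported to
#' 0.001 Angstrom. A role tagged in `site$ring` is reported as the mean
#' distance to its ring carbons (pi coordination) and flagged; an absent
#' role is `NA` with flag `"position not occupied"`.
#'
#' @param site A [site_model()].
#' @return One-row data frame: the six distances (columns named after the
#'   roles), plus `flags` (semicolon-separated) and `denticity` is *not*
#'   included here (see [denticity()]).
#' @export
cu_distances <- function(site) {
  stopifnot(inherits(site, "site_model"))
  out <- as.list(rep(NA_real_, length(SITE_ROLES)))
  names(out) <- SITE_ROLES
  flags <- character()
  for (role in SITE_ROLES) {
    if (!is.null(site$ring) && role %in% names(site$ring)) {
      rc <- as.matrix(site$ring[[role]])
      d <- mean(sqrt(rowSums(sweep(rc, 2, site$cu)^2)))
      out[[role]] <- round(d, 3)
      flags <- c(flags, paste0(role, ": average to ring carbons"))
    } else {
      i <- which(site$donors$role == role)
      if (length(i)) {
        p <- as.numeric(site$donors[i, c("x", "y", "z")])
        out[[role]] <- round(.dist3(site$cu, p), 3)
      } else {
        flags <- c(flags, paste0(role, ": position not occupied"))
      }
    }
  }
  cbind(as.data.frame(out),
        data.frame(flags = paste(flags, collapse = "; "),
                   stringsAsFactors = FALSE))
}

#' Axial/equatorial classification of non-brace donors
#'
#' The three nitrogen donors of the histidine brace define the equatorial
#' plane (fitted through their positions). Every other donor is classified
#' by the angle between its Cu-donor vector and that plane: more than 45
#' degrees off-plane is axial, otherwise equatorial (a donor exactly at 45
#' degrees is classified equatorial).
#'
#' @param site A [site_model()] containing the three N donors.
#' @return Data frame `role`, `angle_deg` (to the plane), `class`.
#' @export
classify_axial_equatorial <- function(site) {
  stopifnot(inherits(site, "site_model"))
  nroles <- c("N_im_MeHis1", "N_am_MeHis1", "N_im_His83")
  idx <- match(nroles, site$donors$role)
  if (anyNA(idx))
    stop("the three N donors are required to define the equatorial plane")
  N <- as.matrix(site$donors[idx, c("x", "y", "z")])
  v1 <- N[2, ] - N[1, ]; v2 <- N[3, ] - N[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(nrm^2)) < 1e-10 * max(sqrt(sum(v1^2)), sqrt(sum(v2^2))))
    stop("collinear N donors: equatorial plane undefined")
  nrm <- nrm / sqrt(sum(nrm^2))
  others <- setdiff(site$donors$role, nroles)
  res <- lapply(others, function(role) {
    p <- as.numeric(site$donors[site$donors$role == role, c("x", "y", "z")])
    v <- p - site$cu
    ang <- asin(min(1, abs(sum(v * nrm)) / sqrt(sum(v^2)))) * 180 / pi
    # tie at the 45-degree boundary resolves to equatorial
    data.frame(role = role, angle_deg = ang,
               class = if (ang > 45 + 1e-9) "axial" else "equatorial",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Ligand denticity at the copper
#'
#' Counts tagged ligand donor atoms within the bond cutoff of Cu. The
#' default 2.6 Angstrom covers observed coordinate bonds up to ~2.53
#' Angstrom while excluding dissociated positions (2.8 Angstrom and
#' beyond).
#'
#' @param site A [site_model()] with `ligand_atoms` (donor atoms flagged
#'   via `is_donor`).
#' @param bond_cutoff Cu-donor bond cutoff, Angstrom.
#' @return List: `count` (0-3+), `label` (`"unbound"`, `"monodentate"`,
#'   `"bidentate"`, `"tridentate"`), `distances` (named, all tagged donor
#'   atoms).
#' @export
denticity <- function(site, bond_cutoff = 2.6) {
  stopifnot(inherits(site, "site_model"))
  la <- site$ligand_atoms
  if (is.null(la) || !nrow(la <- as.data.frame(la)))
    return(list(count = 0L, label = "unbound",
                distances = stats::setNames(numeric(0), character(0))))
  don <- la[as.logical(la$is_donor), , drop = FALSE]
  d <- apply(as.matrix(don[c("x", "y", "z")]), 1,
             function(p) .dist3(site$cu, p))
  names(d) <- don$name
  count <- sum(d <= bond_cutoff)
  label <- c("unbound", "monodentate", "bidentate", "tridentate")[
    min(count, 3L) + 1L]
  list(count = as.integer(count), label = label, distances = d)
}

#' Hydrogen-bond contacts around the bound ligand
#'
#' All (polar hydrogen, acceptor) pairs with an H...acceptor distance at
#' most `d_max`, excluding each hydrogen's covalent partner. Acceptors are
#' the O/N donor atoms of the site plus O/N ligand atoms.
#'
#' @param site A [site_model()] with polar `hydrogens`.
#' @param d_max Maximum H...acceptor distance, Angstrom (default 2.2).
#' @return Data frame `hydrogen`, `acceptor`, `distance` (possibly empty).
#' @export
hbond_contacts <- function(site, d_max = 2.2) {
  stopifnot(inherits(site, "site_model"))
  hy <- site$hydrogens
  empty <- data.frame(hydrogen = character(), acceptor = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (is.null(hy) || !nrow(hy <- as.data.frame(hy))) return(empty)

  acc <- data.frame(name = site$donors$role,
                    x = site$donors$x, y = site$donors$y, z = site$donors$z,
                    stringsAsFactors = FALSE)
  acc <- acc[grepl("^N|^O", acc$name), , drop = FALSE]
  la <- site$ligand_atoms
  if (!is.null(la) && nrow(la <- as.data.frame(la))) {
    lacc <- la[toupper(la$element) %in% c("O", "N"), , drop = FALSE]
    if (nrow(lacc))
      acc <- rbind(acc, data.frame(name = lacc$name, x = lacc$x,
                                   y = lacc$y, z = lacc$z,
                                   stringsAsFactors = FALSE))
  }
  if (!nrow(acc)) return(empty)

  out <- empty
  for (i in seq_len(nrow(hy))) {
    hp <- as.numeric(hy[i, c("x", "y", "z")])
    for (j in seq_len(nrow(acc))) {
      if (identical(acc$name[j], hy$partner[i])) next
      d <- .dist3(hp, as.numeric(acc[j, c("x", "y", "z")]))
      if (d <= d_max)
        out <- rbind(out, data.frame(hydrogen = hy$name[i],
                                     acceptor = acc$name[j], distance = d,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Build a copper-site model from a PDB structure
#'
#' Reads a single-structure PDB (via bio3d) and maps atoms to site roles
#' using a JSON mapping file of the form
#' `{"cu": {"resno": 500, "elety": "CU"},
#'   "roles": {"N_im_MeHis1": {"resno": 1, "elety": "ND1"}, ...},
#'   "ligand": {"resid": "OXL", "donors": ["O1", "O2"]}}`.
#'
#' @param path PDB file.
#' @param map Path to the JSON role-mapping file.
#' @return A [site_model()].
#' @export
read_site_pdb <- function(path, map) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  md <- jsonlite::read_json(map, simplifyVector = TRUE)
  pick <- function(sel) {
    hit <- rep(TRUE, nrow(at))
    if (!is.null(sel$resno)) hit <- hit & at$resno == sel$resno
    if (!is.null(sel$resid)) hit <- hit & at$resid == sel$resid
    if (!is.null(sel$elety)) hit <- hit & at$elety == sel$elety
    if (!is.null(sel$chain)) hit <- hit & at$chain == sel$chain
    which(hit)
  }
  icu <- pick(md$cu)
  if (length(icu) != 1L) stop("Cu selection matched ", length(icu), " atoms")
  cu <- as.numeric(at[icu, c("x", "y", "z")])
  donors <- do.call(rbind, lapply(names(md$roles), function(role) {
    i <- pick(md$roles[[role]])
    if (length(i) != 1L)
      stop("role ", role, " matched ", length(i), " atoms")
    data.frame(role = role, x = at$x[i], y = at$y[i], z = at$z[i],
               stringsAsFactors = FALSE)
  }))
  ligand <- NULL
  if (!is.null(md$ligand)) {
    li <- which(at$resid == md$ligand$resid)
    if (length(li))
      ligand <- data.frame(name = at$elety[li],
                           element = substr(at$elety[li], 1, 1),
                           is_donor = at$elety[li] %in% md$ligand$donors,
                           x = at$x[li], y = at$y[li], z = at$z[li],
                           stringsAsFactors = FALSE)
  }
  site_model(cu, donors, ligand_atoms = ligand)
}
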