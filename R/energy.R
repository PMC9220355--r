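#' @title Species energy tables for the ligand-Cu(II) thermodynamic cycle
#'
#' @description
#' Binding energies are assembled from total electronic energies of three
#' species — the active-site/ligand complex (`AL`), the bare active site
#' (`A`) and the free ligand (`L`) — each evaluated in a stated geometry
#' (`native` = own optimized monomer geometry, `complex` = geometry adopted
#' inside the dimer), basis (`own`, or `complex` for ghost-basis
#' counterpoise evaluations) and continuum solvent (`DEE`, the
#' diethyl-ether protein-like medium, or `water`). A long-format table with
#' one row per (ligand, species, geometry, basis, solvent) is the package's
#' ledger of these energies.
#'
#' Eight slots are referenced per ligand:
#' \itemize{
#'   \item `AL / native / own / DEE` — optimized complex
#'   \item `A / native / own / DEE`, `L / native / own / water`,
#'     `L / native / own / DEE` — optimized monomers
#'   \item `A / complex / own / DEE`, `L / complex / own / DEE` — monomers
#'     frozen at the dimer geometry
#'   \item `A / complex / complex / DEE`, `L / complex / complex / DEE` —
#'     the same geometries with the full dimer (ghost) basis
#' }
#'
#' @name energy-ledger
NULL

.SPECIES  <- c("AL", "A", "L")
.GEOMETRY <- c("native", "complex")
.BASIS    <- c("own", "complex")
.SOLVENT  <- c("DEE", "water")

#' Validate a species energy table
#'
#' Checks column presence, factor levels, finiteness and uniqueness of the
#' (ligand, species, geometry, basis, solvent) key. Rows with
#' `ligand_id == "*"` describe a shared active-site (`A`) block that
#' applies to every ligand.
#'
#' @param records Data frame with columns `ligand_id`, `species`,
#'   `geometry`, `basis`, `solvent`, `energy` (kJ/mol).
#' @return The validated data frame, invisibly classed `energy_table`.
#' @export
energy_table <- function(records) {
  need <- c("ligand_id", "species", "geometry", "basis", "solvent", "energy")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$ligand_id <- as.character(records$ligand_id)
  for (col in c("species", "geometry", "basis", "solvent")) {
    records[[col]] <- as.character(records[[col]])
    ok <- switch(col, species = .SPECIES, geometry = .GEOMETRY,
                 basis = .BASIS, solvent = .SOLVENT)
    bad <- setdiff(unique(records[[col]]), ok)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(records$energy)))
    stop("non-finite energies in table")
  key <- do.call(paste, c(records[c("ligand_id", "species", "geometry",
                                    "basis", "solvent")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (ligand, species, geometry, basis, solvent) rows")
  class(records) <- c("energy_table", "data.frame")
  records
}

#' Read a species energy table from CSV
#'
#' Long-format CSV with columns `ligand_id, species, geometry, basis,
#' solvent, energy` and optionally `unit` (default hartree, the
#' quantum-chemistry convention; values are converted to kJ/mol on ingest).
#'
#' @param path CSV file path.
#' @param default_unit Unit assumed when the file has no `unit` column.
#' @return An `energy_table` data frame (energies in kJ/mol).
#' @export
read_energy_table <- function(path, default_unit = "hartree") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit <- if ("unit" %in% names(df)) df$unit else default_unit
  df$energy <- convert_energy(df$energy, unit)
  df$unit <- NULL
  energy_table(df)
}

#' Read thermal free-energy corrections from CSV
#'
#' Columns `ligand_id, species, g_corr` and optionally `unit`
#' (default hartree). One row per (ligand, species).
#'
#' @param path CSV file path.
#' @param default_unit Unit assumed when the file has no `unit` column.
#' @return Data frame with `ligand_id`, `species`, `g_corr` (kJ/mol).
#' @export
read_thermal_table <- function(path, default_unit = "hartree") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "species", "g_corr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("thermal table lacks column(s): ", paste(miss, collapse = ", "))
  unit <- if ("unit" %in% names(df)) df$unit else default_unit
  df$g_corr <- convert_energy(df$g_corr, unit)
  df$unit <- NULL
  thermal_table(df)
}

#' @rdname read_thermal_table
#' @param corrections Data frame to validate in place of a file.
#' @export
thermal_table <- function(corrections) {
  need <- c("ligand_id", "species", "g_corr")
  corrections <- as.data.frame(corrections)[need]
  corrections$ligand_id <- as.character(corrections$ligand_id)
  corrections$species <- as.character(corrections$species)
  bad <- setdiff(unique(corrections$species), .SPECIES)
  if (length(bad)) stop("invalid species value(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(corrections$g_corr))) stop("non-finite thermal corrections")
  key <- paste(corrections$ligand_id, corrections$species, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (ligand, species) thermal rows")
  corrections
}

# Look up one energy slot for `ligand`; rows with ligand_id "*" act as a
# shared active-site block. Errors name the missing slot.
.slot <- function(records, ligand, species, geometry, basis, solvent) {
  hit <- records$species == species & records$geometry == geometry &
    records$basis == basis & records$solvent == solvent &
    records$ligand_id %in% c(ligand, "*")
  e <- records$energy[hit]
  if (length(e) == 0L)
    stop(sprintf("ligand '%s': missing energy slot (%s, %s, %s, %s)",
                 ligand, species, geometry, basis, solvent))
  # a ligand-specific row overrides the shared "*" block
  if (length(e) > 1L) e <- records$energy[hit & records$ligand_id == ligand]
  e[[1L]]
}

#' Counterpoise basis-set superposition error
#'
#' Computes the two counterpoise components from monomer energies evaluated
#' in the dimer (ghost) basis versus their own basis:
#' `dE_bsse_A = E_AL(A) - E_A(A)` and `dE_bsse_L = E_AL(L) - E_L(L)`,
#' with `dE_bsse` their sum. With the default `sign = "printed"` the
#' components are the plain differences above (non-positive, since the
#' larger basis lowers the energy); `sign = "conventional"` negates them so
#' the correction destabilizes the complex, the usual counterpoise
#' direction.
#'
#' @param E_AL_A,E_A_A Active-site energy in dimer basis / own basis, kJ/mol.
#' @param E_AL_L,E_L_L Ligand energy in dimer basis / own basis, kJ/mol.
#' @param sign `"printed"` or `"conventional"`.
#' @return List with `dE_bsse_A`, `dE_bsse_L`, `dE_bsse` (kJ/mol).
#' @export
bsse_correction <- function(E_AL_A, E_A_A, E_AL_L, E_L_L,
                            sign = c("printed", "conventional")) {
  sign <- match.arg(sign)
  for (nm in c("E_AL_A", "E_A_A", "E_AL_L", "E_L_L")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v)))
      stop("missing or non-finite energy: ", nm)
  }
  s <- if (sign == "printed") 1 else -1
  dA <- s * (E_AL_A - E_A_A)
  dL <- s * (E_AL_L - E_L_L)
  list(dE_bsse_A = dA, dE_bsse_L = dL, dE_bsse = dA + dL)
}

#' Total ligand binding energy (direct route)
#'
#' `dE_bind = E(AL_DEE) - E(A_DEE) - E(L_H2O) + dE_bsse`: the complex in
#' the protein-like ether continuum versus the separated site (ether) and
#' ligand (water), counterpoise-corrected.
#'
#' @param records An [energy_table()] containing the ligand's slots.
#' @param ligand Ligand identifier.
#' @param bsse_sign Passed to [bsse_correction()].
#' @return Binding energy in kJ/mol (scalar).
#' @export
binding_energy <- function(records, ligand, bsse_sign = "printed") {
  E_AL  <- .slot(records, ligand, "AL", "native", "own", "DEE")
  E_A   <- .slot(records, ligand, "A",  "native", "own", "DEE")
  E_Lw  <- .slot(records, ligand, "L",  "native", "own", "water")
  bsse  <- bsse_correction(
    .slot(records, ligand, "A", "complex", "complex", "DEE"),
    .slot(records, ligand, "A", "complex", "own",     "DEE"),
    .slot(records, ligand, "L", "complex", "complex", "DEE"),
    .slot(records, ligand, "L", "complex", "own",     "DEE"),
    sign = bsse_sign)
  E_AL - E_A - E_Lw + bsse$dE_bsse
}

#' Decompose a ligand binding energy into physical contributions
#'
#' Splits `dE_bind` into interaction, deformation, dehydration and
#' counterpoise terms:
#' \itemize{
#'   \item `dE_int = E(AL_DEE) - E(A_AL,DEE) - E(L_AL,DEE)` — interaction of
#'     the frozen fragments
#'   \item `dE_def_A = E(A_AL,DEE) - E(A_DEE)`,
#'     `dE_def_L = E(L_AL,DEE) - E(L_DEE)` — strain of adopting the complex
#'     geometry
#'   \item `dE_dehydr_L = E(L_DEE) - E(L_H2O)` — transfer of the ligand
#'     from water to the protein-like ether continuum
#'   \item `dE_bsse_A`, `dE_bsse_L` per [bsse_correction()]
#' }
#' Their sum equals the direct [binding_energy()] route algebraically.
#' If thermal corrections are supplied, `dG_bind_corr =
#' g(AL) - g(A) - g(L)` and `dG_bind = dE_bind + dG_bind_corr` are added;
#' otherwise those fields are `NA` (never zero-filled).
#'
#' @param records An [energy_table()].
#' @param ligand Ligand identifier.
#' @param thermal Optional thermal-correction table (see
#'   [read_thermal_table()]).
#' @param bsse_sign Passed to [bsse_correction()].
#' @return One-row data frame with `ligand_id`, the five contributions, the
#'   BSSE components, `dE_bind`, `dG_bind_corr`, `dG_bind` (kJ/mol).
#' @export
decompose <- function(records, ligand, thermal = NULL,
                      bsse_sign = "printed") {
  E_AL    <- .slot(records, ligand, "AL", "native",  "own", "DEE")
  E_A     <- .slot(records, ligand, "A",  "native",  "own", "DEE")
  E_Lw    <- .slot(records, ligand, "L",  "native",  "own", "water")
  E_Ld    <- .slot(records, ligand, "L",  "native",  "own", "DEE")
  E_Ac    <- .slot(records, ligand, "A",  "complex", "own", "DEE")
  E_Lc    <- .slot(records, ligand, "L",  "complex", "own", "DEE")
  bsse <- bsse_correction(
    .slot(records, ligand, "A", "complex", "complex", "DEE"), E_Ac,
    .slot(records, ligand, "L", "complex", "complex", "DEE"), E_Lc,
    sign = bsse_sign)

  dE_int      <- E_AL - E_Ac - E_Lc
  dE_def_A    <- E_Ac - E_A
  dE_def_L    <- E_Lc - E_Ld
  dE_dehydr_L <- E_Ld - E_Lw
  dE_bind <- dE_int + dE_def_A + dE_def_L + dE_dehydr_L + bsse$dE_bsse

  dG_corr <- NA_real_
  dG_bind <- NA_real_
  if (!is.null(thermal)) {
    thermal <- thermal_table(thermal)
    g <- function(sp) {
      hit <- thermal$species == sp & thermal$ligand_id %in% c(ligand, "*")
      v <- thermal$g_corr[hit]
      if (length(v) == 0L)
        stop(sprintf("ligand '%s': missing thermal correction for %s",
                     ligand, sp))
      if (length(v) > 1L)
        v <- thermal$g_corr[hit & thermal$ligand_id == ligand]
      v[[1L]]
    }
    fe <- binding_free_energy(dE_bind, g("AL"), g("A"), g("L"))
    dG_corr <- fe$dG_bind_corr
    dG_bind <- fe$dG_bind
  }

  data.frame(ligand_id = ligand, dE_int = dE_int, dE_def_A = dE_def_A,
             dE_def_L = dE_def_L, dE_dehydr_L = dE_dehydr_L,
             dE_bsse_A = bsse$dE_bsse_A, dE_bsse_L = bsse$dE_bsse_L,
             dE_bsse = bsse$dE_bsse, dE_bind = dE_bind,
             dG_bind_corr = dG_corr, dG_bind = dG_bind,
             stringsAsFactors = FALSE)
}

#' Decompose every ligand in an energy table
#'
#' @inheritParams decompose
#' @return Data frame with one [decompose()] row per ligand (shared `"*"`
#'   rows are not themselves ligands).
#' @export
decompose_ligands <- function(records, thermal = NULL,
                              bsse_sign = "printed") {
  records <- energy_table(records)
  ligands <- setdiff(unique(records$ligand_id), "*")
  if (!length(ligands)) stop("no ligands in energy table")
  out <- lapply(ligands, function(l)
    decompose(records, l, thermal = thermal, bsse_sign = bsse_sign))
  do.call(rbind, out)
}

#' Thermal correction and binding free energy
#'
#' `dG_bind_corr = dG_corr(AL) - dG_corr(A) - dG_corr(L)` (rigid-rotor /
#' harmonic-oscillator corrections at the working temperature) and
#' `dG_bind = dE_bind + dG_bind_corr`.
#'
#' @param dE_bind Electronic binding energy, kJ/mol.
#' @param g_AL,g_A,g_L Thermal corrections for complex, site, ligand, kJ/mol.
#' @return List with `dG_bind_corr` and `dG_bind`.
#' @export
binding_free_energy <- function(dE_bind, g_AL, g_A, g_L) {
  for (nm in c("dE_bind", "g_AL", "g_A", "g_L")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v)))
      stop("missing or non-finite value: ", nm)
  }
  corr <- g_AL - g_A - g_L
  list(dG_bind_corr = corr, dG_bind = dE_bind + corr)
}

#' Rank ligands by binding energy
#'
#' Orders a decomposition table ascending (most negative = strongest
#' binder first). The sort is stable with ties broken by `ligand_id`
#' lexicographic order.
#'
#' @param decompositions Data frame as returned by [decompose_ligands()].
#' @param by `"dE_bind"` (default) or `"dG_bind"`.
#' @return The reordered data frame with a `rank` column prepended.
#' @export
rank_ligands <- function(decompositions, by = c("dE_bind", "dG_bind")) {
  by <- match.arg(by)
  if (is.null(decompositions) || nrow(decompositions) == 0L)
    stop("empty decomposition table")
  v <- decompositions[[by]]
  if (anyNA(v)) stop("NA values in ", by, "; supply thermal corrections or rank by dE_bind")
  ord <- order(v, decompositions$ligand_id, method = "radix")
  out <- decompositions[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
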