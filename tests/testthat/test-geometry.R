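water_row <- c(N_im_MeHis1 = 1.95, N_am_MeHis1 = 2.05, N_im_His83 = 1.97,
               O_Tyr166 = 2.44, L_eq = 2.07, L_ax = 2.39)

test_that("Cu-donor distances reproduce the reference water row exactly", {
  sm <- gen_site_geometry(water_row)
  row <- cu_distances(sm)
  expect_identical(unlist(row[names(water_row)]), water_row)
  expect_equal(row$flags, "")
})

test_that("geometry operations are rigid-body invariant", {
  set.seed(51)
  sm <- gen_site_geometry(water_row)
  sm$ligand_atoms <- data.frame(name = c("O1", "O2"), element = "O",
                                is_donor = TRUE,
                                x = c(1.978, 0), y = c(0, 2.146), z = 0)
  sm$hydrogens <- data.frame(name = "HE21", partner = "O1",
                             x = 3.0, y = 1.0, z = 0.5)
  for (i in 1:5) {
    R <- random_rotation(); tt <- rnorm(3, sd = 10)
    smt <- transform_site(sm, R, tt)
    expect_equal(unlist(cu_distances(smt)[names(water_row)]),
                 unlist(cu_distances(sm)[names(water_row)]),
                 tolerance = 1e-9)
    expect_equal(denticity(smt)$count, denticity(sm)$count)
    expect_equal(classify_axial_equatorial(smt)$class,
                 classify_axial_equatorial(sm)$class)
    hb0 <- hbond_contacts(sm); hb1 <- hbond_contacts(smt)
    expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
  }
})

test_that("distances match a naive per-pair oracle on random sites", {
  set.seed(53)
  for (i in 1:10) {
    d <- runif(6, 1.8, 3.5)
    sm <- gen_site_geometry(stats::setNames(d, SITE_ROLES))
    got <- unlist(cu_distances(sm)[SITE_ROLES])
    naive <- vapply(SITE_ROLES, function(role) {
      p <- as.numeric(sm$donors[sm$donors$role == role, c("x", "y", "z")])
      round(sqrt(sum((p - sm$cu)^2)), 3)
    }, 0)
    expect_equal(got, naive)
  }
})

test_that("unoccupied and pi-coordinated positions are flagged", {
  sm <- gen_site_geometry(water_row[1:5])   # no L_ax
  row <- cu_distances(sm)
  expect_true(is.na(row$L_ax))
  expect_match(row$flags, "L_ax: position not occupied")

  # phenyl pi coordination: mean distance to ring carbons
  smp <- gen_site_geometry(water_row[1:5])
  ring <- t(vapply(seq(0, 300, by = 60) * pi / 180, function(a)
    c(1.4 * cos(a), 1.4 * sin(a), -3.64), numeric(3)))[1:6, ]
  smp$ring <- list(L_ax = ring)
  rowp <- cu_distances(smp)
  expect_equal(rowp$L_ax, round(mean(sqrt(rowSums(ring^2))), 3))
  expect_match(rowp$flags, "average to ring carbons")
})

test_that("axial/equatorial classification follows the N-donor plane", {
  sm <- gen_site_geometry(water_row)
  cls <- classify_axial_equatorial(sm)
  expect_equal(cls$class[cls$role == "O_Tyr166"], "axial")
  expect_equal(cls$class[cls$role == "L_ax"], "axial")
  expect_equal(cls$class[cls$role == "L_eq"], "equatorial")
  truth <- attr(sm, "truth")$roles
  expect_equal(stats::setNames(cls$class, cls$role)[names(truth)], truth)

  # a donor at exactly 45 degrees is classified equatorial
  sm45 <- gen_site_geometry(water_row[1:3])
  sm45$donors <- rbind(sm45$donors,
                       data.frame(role = "L_eq", x = sqrt(2), y = 0,
                                  z = sqrt(2)))
  cls45 <- classify_axial_equatorial(site_model(sm45$cu, sm45$donors))
  expect_equal(cls45$angle_deg, 45, tolerance = 1e-9)
  expect_equal(cls45$class, "equatorial")

  coll <- site_model(c(0, 0, 0),
                     data.frame(role = c("N_im_MeHis1", "N_am_MeHis1",
                                         "N_im_His83", "L_eq"),
                                x = c(1, 2, 3, 0), y = c(0, 0, 0, 1),
                                z = c(0, 0, 0, 0)))
  expect_error(classify_axial_equatorial(coll), "collinear")
})

test_that("denticity counts bound ligand donors against the cutoff", {
  oxalate <- site_model(c(0, 0, 0),
                        data.frame(role = c("N_im_MeHis1", "N_am_MeHis1",
                                            "N_im_His83"),
                                   x = c(1.98, 0, -2.02), y = c(0, 2.07, 0),
                                   z = 0),
                        ligand_atoms = data.frame(
                          name = c("O1", "O2", "C1", "C2"),
                          element = c("O", "O", "C", "C"),
                          is_donor = c(TRUE, TRUE, FALSE, FALSE),
                          x = c(1.978 * cos(0.3), 0, 2.8, 3.2),
                          y = c(-1.978 * sin(0.3), 0, -1.5, 0.5),
                          z = c(0, -2.146, 0, 0)))
  dent <- denticity(oxalate)
  expect_equal(dent$count, 2L)
  expect_equal(dent$label, "bidentate")
  expect_equal(sort(unname(round(dent$distances[c("O1", "O2")], 3))),
               c(1.978, 2.146))

  far <- site_model(c(0, 0, 0), oxalate$donors,
                    ligand_atoms = data.frame(name = "O1", element = "O",
                                              is_donor = TRUE,
                                              x = 5, y = 4, z = 4))
  expect_equal(denticity(far)$count, 0L)
  expect_equal(denticity(far)$label, "unbound")
  expect_equal(denticity(site_model(c(0, 0, 0), oxalate$donors))$count, 0L)
})

test_that("denticity steps only at the tabulated bond lengths", {
  # ligand donors at the reference oxalate distances: sweeping the cutoff
  # changes the count exactly at those distances
  d <- c(1.978, 2.146)
  sm <- site_model(c(0, 0, 0),
                   data.frame(role = c("N_im_MeHis1", "N_am_MeHis1",
                                       "N_im_His83"),
                              x = c(2, 0, -2), y = c(0, 2, 0), z = 0),
                   ligand_atoms = data.frame(name = c("O1", "O2"),
                                             element = "O", is_donor = TRUE,
                                             x = d, y = 0, z = 0))
  cuts <- c(1.9, 1.978, 2.0, 2.146, 2.6)
  counts <- vapply(cuts, function(ct) denticity(sm, ct)$count, 0L)
  expect_equal(counts, c(0L, 1L, 1L, 2L, 2L))
  # monotone non-decreasing in the cutoff
  expect_true(all(diff(counts) >= 0))
})

test_that("citrate-like site: long Tyr-O contact counts as dissociated", {
  citrate <- c(N_im_MeHis1 = 1.98, N_am_MeHis1 = 2.06, N_im_His83 = 2.01,
               O_Tyr166 = 3.36, L_eq = 1.95, L_ax = 2.16)
  sm <- gen_site_geometry(citrate)
  row <- cu_distances(sm)
  expect_gt(row$O_Tyr166, 2.6)
  # treated as a ligand donor sweep: the phenolate O is beyond the bond
  # cutoff while the two chelating positions remain bound
  sml <- site_model(sm$cu, sm$donors[sm$donors$role %in%
                                       c("N_im_MeHis1", "N_am_MeHis1",
                                         "N_im_His83"), ],
                    ligand_atoms = data.frame(
                      name = c("O_hydroxyl", "O_carboxyl", "O_phenolate"),
                      element = "O", is_donor = TRUE,
                      x = c(0, 1.95 * cos(1.2), 0),
                      y = c(-1.95, 1.95 * sin(1.2), 0), z = c(0, 0, 3.36)))
  expect_equal(denticity(sml)$label, "bidentate")
})

test_that("hydrogen-bond contacts honor the distance cap and exclusions", {
  base <- gen_site_geometry(water_row)
  base$ligand_atoms <- data.frame(name = c("O_carboxylate", "C1"),
                                  element = c("O", "C"),
                                  is_donor = c(TRUE, FALSE),
                                  x = c(2.0, 3.0), y = c(0.5, 0.5),
                                  z = c(0, 0))
  # amide H of a glutamine placed 1.857 A from the carboxylate oxygen
  base$hydrogens <- data.frame(name = "HE21", partner = "N_gln",
                               x = 2.0 + 1.857, y = 0.5, z = 0)
  hb <- hbond_contacts(base)
  expect_equal(nrow(hb[hb$acceptor == "O_carboxylate", ]), 1L)
  expect_equal(hb$distance[hb$acceptor == "O_carboxylate"], 1.857,
               tolerance = 1e-9)

  base$hydrogens$x <- 2.0 + 3.0
  expect_equal(nrow(hbond_contacts(base)), 0L)

  # covalent partner is never reported as an acceptor
  base$hydrogens <- data.frame(name = "HO", partner = "O_carboxylate",
                               x = 2.0 + 0.97, y = 0.5, z = 0)
  hb2 <- hbond_contacts(base)
  expect_false("O_carboxylate" %in% hb2$acceptor)

  # brute-force all-pairs oracle on a random site
  set.seed(59)
  rnd <- gen_site_geometry(water_row)
  rnd$hydrogens <- data.frame(name = sprintf("H%d", 1:4),
                              partner = "none",
                              x = rnorm(4, 0, 2), y = rnorm(4, 0, 2),
                              z = rnorm(4, 0, 2))
  got <- hbond_contacts(rnd, d_max = 2.2)
  acc <- rnd$donors[grepl("^N|^O", rnd$donors$role), ]
  n_expect <- 0L
  for (i in 1:4) for (j in seq_len(nrow(acc))) {
    dd <- sqrt(sum((as.numeric(rnd$hydrogens[i, c("x", "y", "z")]) -
                      as.numeric(acc[j, c("x", "y", "z")]))^2))
    if (dd <= 2.2) n_expect <- n_expect + 1L
  }
  expect_equal(nrow(got), n_expect)
})

test_that("PDB site ingestion maps roles through the JSON file", {
  sm <- gen_site_geometry(water_row)
  pdb <- tempfile(fileext = ".pdb")
  lines <- character()
  fmt <- "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- c(lines, sprintf(fmt, 1, "CU", "CU", 500,
                            sm$cu[1], sm$cu[2], sm$cu[3], "Cu"))
  ele <- c("ND1", "N", "NE2", "OH", "O1", "O2")
  for (i in seq_len(nrow(sm$donors)))
    lines <- c(lines, sprintf(fmt, i + 1, ele[i], "RES", i,
                              sm$donors$x[i], sm$donors$y[i],
                              sm$donors$z[i],
                              substr(ele[i], 1, 1)))
  writeLines(c(lines, "END"), pdb)
  mapf <- tempfile(fileext = ".json")
  roles <- lapply(seq_along(SITE_ROLES), function(i)
    list(resno = i, elety = ele[i]))
  names(roles) <- SITE_ROLES
  jsonlite::write_json(list(cu = list(elety = "CU"), roles = roles),
                       mapf, auto_unbox = TRUE)
  got <- read_site_pdb(pdb, mapf)
  expect_equal(unlist(cu_distances(got)[names(water_row)]), water_row,
               tolerance = 1e-3)
})
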