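test_that("longest_cn_bond takes the maximum over bonded N-C distances", {
  th <- acos(-1 / 3)
  dirs <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(a)
    c(sin(th) * cos(a), sin(th) * sin(a), cos(th)), numeric(3)))
  m <- molecule(c("N", "C", "C", "C"),
                rbind(c(0, 0, 0), dirs * c(1.47, 1.49, 1.51)))
  expect_equal(longest_cn_bond(m, 1), 1.51, tolerance = 1e-12)
  expect_error(longest_cn_bond(ref_nh3(), 1), "no bonded carbon")
  # one stretched C-N bond is still perceived and reported
  m2 <- molecule(c("N", "C", "C", "C"),
                 rbind(c(0, 0, 0), dirs * c(1.47, 1.47, 1.60)))
  expect_equal(longest_cn_bond(m2, 1), 1.60, tolerance = 1e-12)
})

test_that("molecular_area matches analytic spheres and culls engulfed atoms", {
  m <- molecule("C", matrix(0, 1, 3))
  a1 <- molecular_area(m)
  expect_lt(abs(a1 - 4 * pi * 1.989^2) / (4 * pi * 1.989^2), 0.01)
  # far-apart atoms: additive
  m2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(molecular_area(m2), 2 * a1, tolerance = a1 * 0.01)
  # an H entirely inside the C sphere adds nothing
  m3 <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(0.35, 0, 0)))
  expect_equal(molecular_area(m3), a1, tolerance = a1 * 0.01)
})

test_that("the bundled reference table matches the printed values", {
  tab <- load_reference_table()
  expect_equal(nrow(tab), 47L)
  expect_identical(names(tab), c("amine_id", "dg_h_free", "dg_h_acoh",
                                 "dg_au", "dg_pd0", "dg_pd2", "vbur_total"))
  expect_false(anyDuplicated(tab$amine_id) > 0)

  r1 <- tab[tab$amine_id == "1", ]
  expect_equal(unlist(r1[-1], use.names = FALSE),
               c(-0.3, 22.8, 24.0, 13.8, 3.9, 49.8))
  r36 <- tab[tab$amine_id == "36", ]
  expect_true(is.na(r36$dg_au) && is.na(r36$dg_pd2))
  expect_equal(r36$vbur_total, 70.3)
  expect_equal(r36$dg_pd0, 17.3)
  expect_equal(tab$vbur_total[tab$amine_id == "NH3"], 15.2)
  expect_equal(tab$dg_h_acoh[tab$amine_id == "26"], 53.7)
  expect_equal(tab$dg_pd2[tab$amine_id == "2"], -12.7)
  expect_equal(tab$vbur_total[tab$amine_id == "28"], 65.6)

  # missing-cell census of the printed table
  expect_equal(sum(!is.na(tab$dg_pd2)), 16L)
  expect_equal(sum(!is.na(tab$dg_pd0)), 36L)
  expect_equal(sum(!is.na(tab$dg_au)), 41L)
  expect_equal(sum(!is.na(tab$dg_h_acoh)), 47L)
  expect_true(all(tab$vbur_total >= 0 & tab$vbur_total <= 100))
})

test_that("assemble_table fills geometry columns and joins external data", {
  amines <- list(a1 = build_amine(c("Me", "Me", "Me"), 0.44),
                 a2 = build_amine(c("Et", "Me", "H"), 0.40),
                 a3 = build_amine(c("Et", "Et", "Et"), 0.42))
  man <- data.frame(amine_id = names(amines), role = "amine",
                    path = vapply(amines, write_tmp_xyz, ""),
                    n_index = 1L, stringsAsFactors = FALSE)
  ext <- data.frame(amine_id = c("a1", "a3"), e_lumo = c(-0.01, -0.02),
                    pka = c(10.5, 11.2))
  tab <- assemble_table(man, external = ext, mesh = 0.2)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("vbur_total", "vbur_low", "vbur_high", "pyramidalization",
                    "longest_cn", "molecular_area", "e_lumo", "pka")
                  %in% names(tab)))
  expect_false(any(is.na(tab$vbur_total)))
  expect_equal(tab$pyramidalization, c(0.44, 0.40, 0.42), tolerance = 1e-10)
  expect_equal(tab$e_lumo[tab$amine_id == "a2"], NA_real_)
  expect_equal(tab$pka[tab$amine_id == "a3"], 11.2)
  # ammonium-only columns were never created
  expect_false("vbur_total_ammonium" %in% names(tab))
  prov <- attr(tab, "provenance")
  expect_true(is.data.frame(prov) && nrow(prov) > 0)

  # order independence of the manifest
  tab2 <- assemble_table(man[c(3, 1, 2), ], external = ext, mesh = 0.2)
  tab2 <- tab2[match(tab$amine_id, tab2$amine_id), names(tab)]
  rownames(tab2) <- NULL
  expect_equal(tab, tab2, ignore_attr = TRUE)

  expect_error(assemble_table(rbind(man, man[1, ]), mesh = 0.2), "duplicate")
  bad <- ext; bad$e_lumo <- as.character(bad$e_lumo)
  expect_error(assemble_table(man, external = bad, mesh = 0.2), "non-numeric")
})

test_that("ammonium and metal-complex roles contribute their columns", {
  a <- build_amine(c("Me", "Me", "Me"), 0.45)
  npos <- a$coords[1, ]
  ammonium <- molecule(c(a$elements, "H"), rbind(a$coords, npos + c(0, 0, 1.03)),
                       charge = 1L)
  au <- molecule(c(a$elements, "Au"), rbind(a$coords, npos + c(0, 0, 2.12)))
  pd <- molecule(c(a$elements, "Pd"), rbind(a$coords, npos + c(0, 0, 2.12)))
  man <- data.frame(
    amine_id = "a1",
    role = c("amine", "ammonium", "au_complex", "pd0_complex"),
    path = c(write_tmp_xyz(a), write_tmp_xyz(ammonium),
             write_tmp_xyz(au), write_tmp_xyz(pd)),
    n_index = 1L,
    metal_index = c(NA, NA, n_atoms(au), n_atoms(pd)),
    stringsAsFactors = FALSE)
  tab <- assemble_table(man, mesh = 0.2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$d_n_h, 1.03, tolerance = 1e-10)
  expect_equal(tab$d_au_n, 2.12, tolerance = 1e-10)
  expect_equal(tab$d_pd_n, 2.12, tolerance = 1e-10)
  expect_equal(tab$pyramidalization_pd, tab$pyramidalization,
               tolerance = 1e-10)
  expect_gt(tab$vbur_total_ammonium, tab$vbur_total)  # the proton counts
})
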