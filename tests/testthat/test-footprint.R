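# Contact detection, P/M/PM classification, shares, polar labels, SASA/BSA

test_that("contact cutoff is inclusive and strict at the threshold", {
  expect_equal(nrow(find_contacts(mini_complex(3.90))), 1L)
  expect_equal(nrow(find_contacts(mini_complex(4.10))), 0L)
  expect_equal(nrow(find_contacts(mini_complex(4.00))), 1L)  # inclusive
  expect_error(find_contacts(mini_complex(), cutoff = -1), "positive")
})

test_that("find_contacts equals a brute-force all-pairs scan", {
  for (tpl in c("25d116-ova-kb", "ma2-mart1-a2")) {
    cx <- template_complex(tpl)
    got <- find_contacts(cx)
    bf <- brute_force_contacts(cx)
    expect_equal(nrow(got), bf$n)
    keys <- sort(paste(got$ab_chain, got$ab_resno, got$ab_atom,
                       got$target_chain, got$target_resno, got$target_atom))
    expect_equal(keys, bf$keys)
  }
})

test_that("contacts are monotone in the cutoff", {
  cx <- template_complex("3m4e5-nyeso-a2")
  key <- function(ct) paste(ct$ab_chain, ct$ab_resno, ct$ab_atom,
                            ct$target_chain, ct$target_resno, ct$target_atom)
  small <- find_contacts(cx, cutoff = 3.5)
  big <- find_contacts(cx, cutoff = 4.0)
  bigger <- find_contacts(cx, cutoff = 5.0)
  expect_true(all(key(small) %in% key(big)))
  expect_true(all(key(big) %in% key(bigger)))
})

test_that("contacts, classes, shares and BSA are rigid-motion invariant", {
  cx <- template_complex("ma2-mart1-a2")
  R <- rotation_matrix(c(1, 2, 3), 37)
  moved <- transform_complex(cx, R, c(5, -3, 2))
  ct0 <- find_contacts(cx); ct1 <- find_contacts(moved)
  expect_equal(nrow(ct1), nrow(ct0))
  expect_equal(ct1$distance, ct0$distance, tolerance = 1e-9)
  expect_equal(classify_ab_residues(ct1)$class,
               classify_ab_residues(ct0)$class)
  expect_equal(mhc_residue_share(ct1, c(65, 146, 151)),
               mhc_residue_share(ct0, c(65, 146, 151)))
  b0 <- buried_surface(cx); b1 <- buried_surface(moved)
  expect_equal(b1$bsa_peptide, b0$bsa_peptide, tolerance = 0.03)
  expect_equal(b1$bsa_mhc, b0$bsa_mhc, tolerance = 0.03)
})

test_that("side_chain_only drops peptide backbone but keeps glycine CA", {
  cx <- template_complex("3m4e5-nyeso-a2")
  all_atom <- classify_ab_residues(find_contacts(cx, restrict_to_cdrs = TRUE))
  sc <- classify_ab_residues(find_contacts(cx, side_chain_only = TRUE,
                                           restrict_to_cdrs = TRUE))
  # H100 was designed to contact only the peptide backbone carbonyl
  expect_true(any(all_atom$chain == "H" & all_atom$resno == 100 &
                    all_atom$n_contacts_peptide > 0))
  expect_false(any(sc$chain == "H" & sc$resno == 100 &
                     sc$n_contacts_peptide > 0))
  # glycine CA counts as side chain: MA2 stand-in contacts P4/P6 glycines
  ma2 <- template_complex("ma2-mart1-a2")
  sc2 <- find_contacts(ma2, side_chain_only = TRUE)
  expect_true(any(sc2$peptide_position == "P4" & sc2$target_atom == "CA",
                  na.rm = TRUE))
})

test_that("classification partitions P/M/PM consistently with counts", {
  for (tpl in c("25d116-ova-kb", "3m4e5-nyeso-a2", "ma2-mart1-a2")) {
    fp <- classify_ab_residues(find_contacts(template_complex(tpl)))
    expect_true(all(fp$n_contacts_peptide + fp$n_contacts_mhc > 0))
    expect_equal(fp$class,
                 ifelse(fp$n_contacts_peptide > 0 & fp$n_contacts_mhc > 0,
                        "PM",
                        ifelse(fp$n_contacts_peptide > 0, "P", "M")))
    expect_false(is.unsorted(fp$resno[fp$chain == "H"]))
  }
  # single-target residue is class P by definition
  fp1 <- classify_ab_residues(find_contacts(mini_complex(3.5)))
  expect_equal(fp1$class, "P")
})

test_that("mhc_residue_share handles completeness and zero-contact errors", {
  ct <- find_contacts(template_complex("ma2-mart1-a2"))
  all_res <- unique(ct$target_resno[ct$target_role == "MHC"])
  expect_equal(mhc_residue_share(ct, all_res), 1.0)
  expect_equal(mhc_residue_share(ct, c("R65", "K146", "H151")),
               mhc_residue_share(ct, c(65, 146, 151)))
  ct_pep_only <- find_contacts(mini_complex(3.5))
  expect_error(mhc_residue_share(ct_pep_only, 65), "no antibody-MHC")
})

test_that("polar contact labels follow the geometric definitions", {
  mk <- function(ab_atom, tg_atom, ab_resid, tg_resid, d) {
    ct <- data.frame(ab_chain = "H", ab_resno = 1L, ab_insert = "",
                     ab_resid = ab_resid, ab_atom = ab_atom, ab_cdr = "FR",
                     target_role = "PEPTIDE", target_chain = "C",
                     target_resno = 1L, target_resid = tg_resid,
                     target_atom = tg_atom, peptide_position = "P1",
                     distance = d, polar_class = "vdw",
                     stringsAsFactors = FALSE)
    class(ct) <- c("contact_table", "data.frame")
    ct
  }
  expect_equal(polar_contacts(NULL, mk("N", "O", "ALA", "ALA", 2.9))$polar_class,
               "hbond")
  expect_equal(polar_contacts(NULL, mk("NH1", "OE1", "ARG", "GLU", 3.8))$polar_class,
               "saltbridge")
  expect_equal(polar_contacts(NULL, mk("CB", "CG", "ALA", "LEU", 3.4))$polar_class,
               "vdw")
  # hbond requires the tighter cutoff
  expect_equal(polar_contacts(NULL, mk("N", "O", "ALA", "ALA", 3.8))$polar_class,
               "vdw")
})

test_that("SASA matches closed forms for isolated and paired spheres", {
  one <- sasa_atoms(matrix(0, 1, 3), radii = 1.7)
  expect_equal(one, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  # two equal spheres at distance d: exposed = 4*pi*R^2 - 2*pi*R*h,
  # h = R - d/2 (spherical cap closed form)
  R <- 1.7 + 1.4; d <- 2.0
  two <- sasa_atoms(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE),
                    radii = c(1.7, 1.7))
  expect_equal(two, rep(4 * pi * R^2 - 2 * pi * R * (R - d / 2), 2),
               tolerance = 0.01)
})

test_that("SASA agrees with an independent implementation on a random cloud", {
  set.seed(3)
  n <- 40
  xyz <- matrix(runif(3 * n, 0, 8), n, 3)
  radii <- rep(1.7, n)
  ours <- sasa_atoms(xyz, radii)
  script <- sprintf(paste0(
    "import numpy as np, biotite.structure as struc\n",
    "xyz = np.array(%s).reshape(%d, 3)\n",
    "arr = struc.AtomArray(%d)\n",
    "arr.coord = xyz\n",
    "arr.element = np.array(['C'] * %d)\n",
    "s = struc.sasa(arr, probe_radius=1.4, point_number=960, ",
    "vdw_radii=np.full(%d, 1.7))\n",
    "print(float(s.sum()))\n"),
    paste0("[", paste(sprintf("%.6f", t(xyz)), collapse = ","), "]"),
    n, n, n, n)
  ref <- suppressWarnings(
    as.numeric(system2("python", c("-c", shQuote(script)), stdout = TRUE)))
  expect_true(is.finite(ref))
  expect_equal(sum(ours), ref, tolerance = 0.05)
})

test_that("buried surface splits into positive peptide and MHC portions", {
  bs <- buried_surface(template_complex("ma2-mart1-a2"))
  expect_gt(bs$bsa_peptide, 0)
  expect_gt(bs$bsa_mhc, 0)
  # fully separated interface buries nothing
  apart <- build_synthetic_complex("SIINFEKL")
  bs0 <- buried_surface(apart)
  expect_equal(bs0$bsa_peptide, 0)
  expect_equal(bs0$bsa_mhc, 0)
})

test_that("footprint report summarizes counts, CDR shares and MHC residues", {
  rep <- footprint_report(template_complex("ma2-mart1-a2"))
  s <- rep$summary
  expect_equal(s$n_contacts_peptide + s$n_contacts_mhc, s$n_contacts_total)
  pc <- s$per_cdr_mhc
  expect_equal(sum(pc$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(pc$n_contacts), s$n_contacts_mhc)
  expect_output(print(rep), "Interface footprint")
  rec <- as_record(rep)
  expect_true(is.list(rec$summary))
})
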