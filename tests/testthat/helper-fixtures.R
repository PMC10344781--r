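# Shared fixtures: synthetic stand-in complexes are deterministic but take a
# moment to build, so cache them per test session.

.fixture_cache <- new.env(parent = emptyenv())

template_complex <- function(name) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- synthetic_tcrm_complex(name)
  .fixture_cache[[name]]
}

# Minimal hand-made complex: one antibody atom at distance `d` from one
# peptide CB atom, plus far-away MHC/B2M filler so roles are well-formed.
mini_complex <- function(d = 3.9) {
  atoms <- data.frame(
    chain = c("C", "C", "A", "H", "L"),
    resno = c(1L, 1L, 1L, 1L, 1L),
    insert = "", resid = c("ALA", "ALA", "ALA", "ALA", "ALA"),
    elety = c("CA", "CB", "CA", "CB", "CB"),
    elesy = "C",
    x = c(0, 0, 50, d, 100), y = c(0, 0, 0, 0, 100),
    z = c(0, 1, 0, 1, 0),
    o = 1, alt = "", is_het = FALSE, is_water = FALSE,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 roles = c(A = "MHC_HEAVY", C = "PEPTIDE",
                           H = "AB_HEAVY", L = "AB_LIGHT"),
                 peptide_positions = c(P1 = 1L),
                 cdr = NULL, meta = list(source = "mini")),
            class = "tcrm_complex")
}

# Hand-written two-conformer PDB fixture (alt-locs A occ 0.6 / B occ 0.4)
altloc_pdb <- function(path) {
  fmt <- "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, 1, " N", " ", "ALA", "A", 1, 0, 0, 0, 1, 0, "N"),
    sprintf(fmt, 2, " CA", "A", "ALA", "A", 1, 1.5, 0, 0, 0.6, 0, "C"),
    sprintf(fmt, 3, " CA", "B", "ALA", "A", 1, 1.7, 0.2, 0, 0.4, 0, "C"),
    sprintf(fmt, 4, " C", " ", "ALA", "A", 1, 2.5, 1, 0, 1, 0, "C"),
    sprintf(fmt, 5, " O", " ", "ALA", "A", 1, 3.5, 1, 0.5, 1, 0, "O"),
    sprintf(fmt, 6, " CB", " ", "ALA", "A", 1, 1.5, -1.4, 0, 1, 0, "C"),
    "END")
  writeLines(lines, path)
  path
}

# Independent brute-force contact scan: plain nested loop, no vectorization
# shared with the implementation.
brute_force_contacts <- function(complex, cutoff = 4.0) {
  at <- complex$atoms
  at <- at[!at$is_water & !at$is_het & at$elesy != "H", ]
  ab <- at[complex$roles[at$chain] %in% c("AB_HEAVY", "AB_LIGHT"), ]
  tg <- at[complex$roles[at$chain] %in% c("PEPTIDE", "MHC_HEAVY"), ]
  n <- 0L
  keys <- character(0)
  for (i in seq_len(nrow(ab))) {
    for (j in seq_len(nrow(tg))) {
      dd <- sqrt((ab$x[i] - tg$x[j])^2 + (ab$y[i] - tg$y[j])^2 +
                   (ab$z[i] - tg$z[j])^2)
      if (dd <= cutoff) {
        n <- n + 1L
        keys <- c(keys, paste(ab$chain[i], ab$resno[i], ab$elety[i],
                              tg$chain[j], tg$resno[j], tg$elety[j]))
      }
    }
  }
  list(n = n, keys = sort(keys))
}

# Simulated pipeline density estimate for one seed/density setting
estimate_density_once <- function(density, seed, field = c(12, 12),
                                  immobile_density = 0.1) {
  cfg <- sim_config(true_density = density, field = field,
                    diffusion_coeff = 0.1, bleach_prob = 0.02,
                    detection_prob = 0.9, immobile_density = immobile_density,
                    seed = seed)
  sim <- simulate_smlm(cfg)
  res <- quantify_density(sim$table, quant_config(vCSA = prod(field)))
  c(est = res$rho, truth = sim$truth$n_mobile / prod(field))
}
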