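# small in-code fixtures shared across test files

tiny_counts <- function() {
  m <- matrix(c(5, 0, 3, 1,
                0, 2, 0, 4,
                1, 1, 1, 0), nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("c1", "c2", "c3")))
  vr_counts(m)
}

tiny_catalog <- function() {
  gene_catalog(data.frame(
    gene_id = c("Vmn1r1", "Vmn1r2", "Vmn2r1", "Vmn2r2", "Vmn2r3",
                "Vmn2r8", "H2-M1", "Gnao1", "Gnai2", "Gap43", "Ascl1",
                "Neurod1", "mt-Nd1", "Hbb-bs", "Bg1", "Bg2"),
    class = c("V1R", "V1R", "V2R_C1", "V2R_C2", "V2R_C2", "V2R_ABDE",
              "H2Mv", "marker", "marker", "marker", "marker", "marker",
              "mito", "hemoglobin", "other", "other"),
    subfamily = ""))
}

# a small, fast simulated dataset for unit tests; the background panel
# is shrunk with its per-gene scale raised so library sizes (and hence
# the normalized-value scale) stay at the default's magnitude
small_sim <- function(seed = 11L, ...) {
  generate_dataset(sim_config(
    n_cells = c(mature_Gnao1 = 300, mature_Gnai2 = 300,
                immature_Gnao1 = 100, immature_Gnai2 = 100,
                progenitor = 60, other = 60),
    n_background = 400, bg_scale = 37.5, seed = seed, ...))
}

# norm matrix + truth-labelled mature cells from a simulated dataset
sim_norm_labels <- function(sim) {
  qc <- compute_qc(sim$counts, sim$catalog)
  filtered <- filter_cells(sim$counts, qc)
  norm <- lognormalize(filtered)
  labels <- classify_cells(norm, sim$catalog)
  list(norm = norm, labels = labels)
}

# a calls object built from planted sets directly (no expression), for
# combinatorics tests with exact control over the per-cell sets
calls_from_sets <- function(sets) {
  rows <- lapply(names(sets), function(bc) {
    s <- sets[[bc]]
    if (!length(s)) return(NULL)
    data.frame(barcode = bc,
               gene = sub("^[^:]+:", "", s),
               family = sub(":.*$", "", s),
               value = 2, stringsAsFactors = FALSE)
  })
  empty <- data.frame(barcode = character(0), gene = character(0),
                      family = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  structure(list(cells = names(sets),
                 calls = do.call(rbind, c(list(empty), rows))),
            class = "vr_calls")
}
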