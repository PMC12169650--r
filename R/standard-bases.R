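# Embedded standard reference-frame geometries for the four bases
# (Tsukuba-convention standard bases; heavy atoms only, coordinates in the
# base's own standard frame, Angstrom). The C1' position is included so the
# sugar can be grafted in the same frame. x points into the major groove,
# y along the pseudo-dyad towards the backbone, z completes the right-handed
# set; an ideal Watson-Crick pair is formed by a flipped copy of the
# complementary base in the coincident frame.

std_base_coords <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346, 0.000),
    N9  = c(-1.291, 4.498, 0.000),
    C8  = c( 0.024, 4.897, 0.000),
    N7  = c( 0.877, 3.902, 0.000),
    C5  = c( 0.071, 2.771, 0.000),
    C6  = c( 0.369, 1.398, 0.000),
    N6  = c( 1.611, 0.909, 0.000),
    N1  = c(-0.668, 0.532, 0.000),
    C2  = c(-1.912, 1.023, 0.000),
    N3  = c(-2.320, 2.290, 0.000),
    C4  = c(-1.267, 3.124, 0.000)),
  G = rbind(
    "C1'" = c(-2.477, 5.399, 0.000),
    N9  = c(-1.289, 4.551, 0.000),
    C8  = c( 0.023, 4.962, 0.000),
    N7  = c( 0.870, 3.969, 0.000),
    C5  = c( 0.071, 2.833, 0.000),
    C6  = c( 0.424, 1.460, 0.000),
    O6  = c( 1.554, 0.955, 0.000),
    N1  = c(-0.700, 0.641, 0.000),
    C2  = c(-1.999, 1.087, 0.000),
    N2  = c(-2.949, 0.139, 0.000),
    N3  = c(-2.342, 2.364, 0.000),
    C4  = c(-1.265, 3.177, 0.000)),
  C = rbind(
    "C1'" = c(-2.477, 5.402, 0.000),
    N1  = c(-1.285, 4.542, 0.000),
    C2  = c(-1.472, 3.158, 0.000),
    O2  = c(-2.628, 2.709, 0.000),
    N3  = c(-0.391, 2.344, 0.000),
    C4  = c( 0.837, 2.868, 0.000),
    N4  = c( 1.875, 2.027, 0.000),
    C5  = c( 1.056, 4.275, 0.000),
    C6  = c(-0.023, 5.068, 0.000)),
  T = rbind(
    "C1'" = c(-2.481, 5.354, 0.000),
    N1  = c(-1.284, 4.500, 0.000),
    C2  = c(-1.462, 3.135, 0.000),
    O2  = c(-2.562, 2.608, 0.000),
    N3  = c(-0.298, 2.407, 0.000),
    C4  = c( 0.994, 2.897, 0.000),
    O4  = c( 1.944, 2.119, 0.000),
    C5  = c( 1.106, 4.338, 0.000),
    C7  = c( 2.466, 4.961, 0.000),
    C6  = c(-0.024, 5.057, 0.000))
)

base_complement <- c(A = "T", T = "A", G = "C", C = "G")

is_purine <- function(base) base %in% c("A", "G")

# ring atoms used for least-squares frame fitting
base_ring_atoms <- function(base) {
  if (is_purine(base)) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

# glycosidic nitrogen and the base atom completing the chi torsion
glycosidic_atoms <- function(base) {
  if (is_purine(base)) c(n = "N9", ref = "C4") else c(n = "N1", ref = "C2")
}

# minor-groove acceptor atom on the base (sugar O4' handled separately)
minor_groove_acceptor <- function(base) {
  if (is_purine(base)) "N3" else "O2"
}

sugar_ring_atom_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
sugar_atom_names <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'")

# Watson-Crick donor/acceptor heavy-atom pairs (watson_atom, crick_atom)
wc_hbond_atoms <- function(watson_base) {
  switch(watson_base,
    A = list(c("N1", "N3"), c("N6", "O4")),
    T = list(c("N3", "N1"), c("O4", "N6")),
    G = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
    C = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
    stop("unknown base: ", watson_base))
}

resid_to_base <- function(resid) {
  map <- c(DA = "A", DT = "T", DG = "G", DC = "C",
           A = "A", T = "T", G = "G", C = "C")
  unname(map[resid])
}

base_to_resid <- function(base) paste0("D", base)
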