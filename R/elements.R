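# Element data: symbol recognition, standard atomic weights, valence model.
#
# Weights are abridged standard atomic weights (CIAAW 2021, four significant
# figures for most elements); frozen here so molecular weights are
# bit-reproducible. Elements without a stable standard weight carry the mass
# number of the longest-lived isotope.

.element_weights <- c(
  H = 1.008,   He = 4.003,  Li = 6.94,   Be = 9.012,  B = 10.81,
  C = 12.011,  N = 14.007,  O = 15.999,  F = 18.998,  Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06,   Cl = 35.45,  Ar = 39.95,  K = 39.098,  Ca = 40.078,
  Sc = 44.956, Ti = 47.867, V = 50.942,  Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Rb = 85.468, Sr = 87.62,  Y = 88.906,  Zr = 91.224,
  Nb = 92.906, Mo = 95.95,  Tc = 97,     Ru = 101.07, Rh = 102.906,
  Pd = 106.42, Ag = 107.868, Cd = 112.414, In = 114.818, Sn = 118.710,
  Sb = 121.760, Te = 127.60, I = 126.904, Xe = 131.293, Cs = 132.905,
  Ba = 137.327, La = 138.905, Ce = 140.116, Pr = 140.908, Nd = 144.242,
  Pm = 145,    Sm = 150.36, Eu = 151.964, Gd = 157.25, Tb = 158.925,
  Dy = 162.500, Ho = 164.930, Er = 167.259, Tm = 168.934, Yb = 173.045,
  Lu = 174.967, Hf = 178.486, Ta = 180.948, W = 183.84, Re = 186.207,
  Os = 190.23, Ir = 192.217, Pt = 195.084, Au = 196.967, Hg = 200.592,
  Tl = 204.38, Pb = 207.2,  Bi = 208.980, Po = 209,    At = 210,
  Rn = 222,    Fr = 223,    Ra = 226,    Ac = 227,    Th = 232.038,
  Pa = 231.036, U = 238.029, Np = 237,   Pu = 244,    Am = 243,
  Cm = 247,    Bk = 247,    Cf = 251,    Es = 252,    Fm = 257,
  Md = 258,    No = 259,    Lr = 262,    Rf = 267,    Db = 268,
  Sg = 269,    Bh = 270,    Hs = 277,    Mt = 278,    Ds = 281,
  Rg = 282,    Cn = 285,    Nh = 286,    Fl = 289,    Mc = 290,
  Lv = 293,    Ts = 294,    Og = 294
)

.element_symbols <- names(.element_weights)

# SMILES organic subset (writable without brackets) and aromatic-capable set.
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_elements <- c("B", "C", "N", "O", "P", "S", "Se", "As")
# lowercase tokens accepted outside brackets
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

# Allowed valence sets for bare (non-bracket) atoms. Bracket atoms are exempt
# from valence errors: the explicit specification wins.
.valence_sets <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

is_known_element <- function(sym) sym %in% .element_symbols

element_weight <- function(sym) {
  w <- .element_weights[sym]
  if (anyNA(w)) stop("no atomic weight for element(s): ",
                     paste(unique(sym[is.na(w)]), collapse = ", "))
  unname(w)
}
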