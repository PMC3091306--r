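# Embedded isotope table (IUPAC 2013 masses / representative natural
# abundances). Kept in the package so all mass arithmetic is reproducible
# offline; first isotope of each element is the most abundant one, which for
# all supported elements is also the monoisotopic (lightest) species.

.electron_mass <- 0.000548579909

.isotope_table <- list(
  C  = list(mass = c(12.0000000, 13.0033548378), abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.0078250319, 2.0141017779), abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = c(30.97376151), abundance = c(1.0)),
  S  = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = c(22.98976928), abundance = c(1.0)),
  K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Li = list(mass = c(7.0160034366, 6.0151228874), abundance = c(0.9241, 0.0759)),
  F  = list(mass = c(18.9984031627), abundance = c(1.0)),
  Cl = list(mass = c(34.968852682, 36.965902602), abundance = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376, 80.9162897), abundance = c(0.5069, 0.4931)),
  I  = list(mass = c(126.9044719), abundance = c(1.0))
)

# Valence used for the generalized double-bond-equivalent term n * (v - 2) / 2.
.element_valence <- c(
  C = 4, H = 1, N = 3, O = 2, P = 3, S = 2,
  Na = 1, K = 1, Li = 1, F = 1, Cl = 1, Br = 1, I = 1
)

.known_elements <- function() names(.isotope_table)

.monoisotopic_mass <- function(symbol) {
  tab <- .isotope_table[[symbol]]
  if (is.null(tab)) stop("unknown element symbol: ", symbol, call. = FALSE)
  tab$mass[1L]
}
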