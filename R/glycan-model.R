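#' Glycan composition objects
#'
#' Compositional model of complex N-glycans in the shorthand used for
#' recombinant glycoprotein comparability work: `[F][Ax][Gy][Sz][LacN]`,
#' where `F` marks a single core alpha(1-6) fucose, `Ax` the number of
#' GlcNAc antennae on the trimannosyl core (1-4), `Gy` the number of
#' beta(1-4) galactoses, `Sz` the number of terminal sialic acids (NeuAc)
#' and `LacN` the number of extra N-acetyllactosamine (Gal-GlcNAc) repeat
#' units extending an antenna. A lac repeat extends an antenna; it does not
#' add one, so it contributes to mass and to the HexNAc/Hex counts but not
#' to the antenna count.
#'
#' The residue composition is fully determined by the five counts:
#' `HexNAc = 2 + antennae + lac`, `Hex = 3 + galactoses + lac`,
#' `dHex = core_fucose`, `NeuAc = sialic_acids`.
#'
#' @param core_fucose 0 or 1.
#' @param antennae Number of antennae, 1-4.
#' @param galactoses Number of antennary galactoses, `>= 0`.
#' @param sialic_acids Number of sialic acids; must not exceed
#'   `galactoses + lac_repeats`.
#' @param lac_repeats Number of N-acetyllactosamine repeats, `>= 0`.
#' @return An object of class `glycan_composition`: a list with the five
#'   count fields plus `canonical_name`.
#' @examples
#' glycan_composition(antennae = 2, galactoses = 2, sialic_acids = 2)
#' parse_glycan_name("FA4G4S3Lac1")
#' @export
glycan_composition <- function(core_fucose = 0L, antennae = 2L,
                               galactoses = 0L, sialic_acids = 0L,
                               lac_repeats = 0L) {
  comp <- list(
    core_fucose  = as.integer(core_fucose),
    antennae     = as.integer(antennae),
    galactoses   = as.integer(galactoses),
    sialic_acids = as.integer(sialic_acids),
    lac_repeats  = as.integer(lac_repeats)
  )
  validate_glycan_composition(comp)
  comp$canonical_name <- .render_name(comp)
  structure(comp, class = "glycan_composition")
}

validate_glycan_composition <- function(comp) {
  with(comp, {
    if (!core_fucose %in% c(0L, 1L))
      stop("core_fucose must be 0 or 1", call. = FALSE)
    if (antennae < 1L || antennae > 4L)
      stop("antennae must be between 1 and 4, got ", antennae, call. = FALSE)
    if (galactoses < 0L || lac_repeats < 0L || sialic_acids < 0L)
      stop("counts must be non-negative", call. = FALSE)
    if (sialic_acids > galactoses + lac_repeats)
      stop("invalid composition: ", sialic_acids, " sialic acids exceed ",
           galactoses + lac_repeats, " available galactoses (incl. lac repeats)",
           call. = FALSE)
  })
  invisible(comp)
}

.render_name <- function(comp) {
  paste0(
    if (comp$core_fucose) "F" else "",
    "A", comp$antennae,
    "G", comp$galactoses,
    "S", comp$sialic_acids,
    if (comp$lac_repeats > 0L) paste0("Lac", comp$lac_repeats) else ""
  )
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", x$canonical_name, "\n", sep = "")
  cat(sprintf("  antennae %d, galactoses %d, sialic acids %d, lac repeats %d, core fucose %d\n",
              x$antennae, x$galactoses, x$sialic_acids, x$lac_repeats,
              x$core_fucose))
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) x$canonical_name

# Known spelling variants mapped to canonical names. "F2A2G2S2" appears in
# published species lists; with a single core-fucosylation site it is read as
# core-fucosylated A2G2S2. The table is extensible via options(
# glycopotency.glycan_aliases = c(alias = canonical)).
.default_glycan_aliases <- c(F2A2G2S2 = "FA2G2S2")

glycan_aliases <- function() {
  c(getOption("glycopotency.glycan_aliases", character()),
    .default_glycan_aliases)
}

#' Parse a glycan shorthand name
#'
#' Parses the `[F][Ax][Gy][Sz][LacN]` dialect into a
#' [glycan_composition()]. `Gy` and `Sz` may be omitted (count 0).
#' A small alias table handles published spelling variants
#' (e.g. `"F2A2G2S2"` for core-fucosylated `"FA2G2S2"`); aliased names are
#' reported via a message so that the substitution is visible in logs.
#'
#' @param name Glycan name, e.g. `"A2G2S2"`, `"FA4G4S3Lac1"`.
#' @param quiet Suppress the alias message.
#' @return A `glycan_composition`.
#' @examples
#' parse_glycan_name("A2G2S2")
#' @export
parse_glycan_name <- function(name, quiet = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  raw <- trimws(name)
  aliases <- glycan_aliases()
  if (raw %in% names(aliases)) {
    if (!quiet)
      message("glycan name '", raw, "' read as alias of '",
              aliases[[raw]], "'")
    raw <- aliases[[raw]]
  }
  m <- regexec("^(F)?A([0-9]+)(?:G([0-9]+))?(?:S([0-9]+))?(?:Lac([0-9]+))?$",
               raw)
  parts <- regmatches(raw, m)[[1]]
  if (!length(parts)) {
    # locate the first offending token for the error message
    ok <- regexpr("^(F)?(A[0-9]+)?(G[0-9]+)?(S[0-9]+)?(Lac[0-9]+)?", raw)
    off <- attr(ok, "match.length") + 1L
    bad <- if (off <= nchar(raw)) substr(raw, off, nchar(raw)) else raw
    stop("cannot parse glycan name '", name, "': unexpected token '",
         bad, "'", call. = FALSE)
  }
  num <- function(s, default = 0L) if (nzchar(s)) as.integer(s) else default
  glycan_composition(
    core_fucose  = as.integer(nzchar(parts[2])),
    antennae     = num(parts[3], NA_integer_),
    galactoses   = num(parts[4]),
    sialic_acids = num(parts[5]),
    lac_repeats  = num(parts[6])
  )
}

#' Render a composition back to its canonical shorthand
#'
#' Inverse of [parse_glycan_name()]: `parse_glycan_name(render_glycan_name(x))`
#' reproduces `x` for every valid composition.
#'
#' @param comp A `glycan_composition`.
#' @return The canonical name, e.g. `"FA2G2S2"`.
#' @export
render_glycan_name <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  comp$canonical_name
}

#' Residue counts of a glycan composition
#'
#' @param comp A `glycan_composition`.
#' @return Named integer vector with `HexNAc`, `Hex`, `dHex`, `NeuAc`.
#' @export
glycan_residue_counts <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  c(HexNAc = 2L + comp$antennae + comp$lac_repeats,
    Hex    = 3L + comp$galactoses + comp$lac_repeats,
    dHex   = comp$core_fucose,
    NeuAc  = comp$sialic_acids)
}

#' Glycan residue mass
#'
#' Mass of the glycan as a residue addition to a peptide (glycosidic bond to
#' the asparagine side chain; no extra water term).
#'
#' @param comp A `glycan_composition` or a glycan name.
#' @param table Mass table from [monosaccharide_masses()].
#' @return Mass in Da.
#' @examples
#' glycan_residue_mass("A2G2S2") # 2204.772
#' @export
glycan_residue_mass <- function(comp, table = monosaccharide_masses()) {
  if (is.character(comp)) comp <- parse_glycan_name(comp, quiet = TRUE)
  counts <- glycan_residue_counts(comp)
  counts[["HexNAc"]] * table$HexNAc + counts[["Hex"]] * table$Hex +
    counts[["dHex"]] * table$dHex + counts[["NeuAc"]] * table$NeuAc
}

#' Export / import glycan composition tables
#'
#' CSV round-trip of a set of compositions with their residue masses:
#' columns `name, fuc, antennae, gal, sia, lac, residue_mass`.
#'
#' @param names Character vector of glycan names.
#' @param file Path to write to / read from.
#' @return `write_glycan_table()` returns the data frame invisibly;
#'   `read_glycan_table()` returns a list of `glycan_composition` objects.
#' @export
write_glycan_table <- function(names, file) {
  comps <- lapply(names, parse_glycan_name, quiet = TRUE)
  df <- data.frame(
    name = vapply(comps, render_glycan_name, character(1)),
    fuc = vapply(comps, function(c) c$core_fucose, integer(1)),
    antennae = vapply(comps, function(c) c$antennae, integer(1)),
    gal = vapply(comps, function(c) c$galactoses, integer(1)),
    sia = vapply(comps, function(c) c$sialic_acids, integer(1)),
    lac = vapply(comps, function(c) c$lac_repeats, integer(1)),
    residue_mass = vapply(comps, glycan_residue_mass, numeric(1))
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname write_glycan_table
#' @export
read_glycan_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  comps <- lapply(df$name, parse_glycan_name, quiet = TRUE)
  names(comps) <- df$name
  comps
}
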