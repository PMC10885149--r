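# Shorthand lipid-name parsing and formula construction for the negative-ion
# sphingolipid / glycerophospholipid panel: CerP, PE-Cer, GM1/GM2/GM3, HexCer,
# ST, PA/LPA/CPA, PE/LPE/PE-P (plasmalogen), PI/LPI.

SPHINGO_CLASSES <- c("Cer", "CerP", "PE-Cer", "HexCer", "ST", "GM1", "GM2", "GM3")
GLYCERO_CLASSES <- c("PA", "LPA", "CPA", "PE", "LPE", "PE-P", "PI", "LPI")
LIPID_CLASSES <- c(SPHINGO_CLASSES, GLYCERO_CLASSES)

# Residue formulas used by the construction rules. Sugar and sialic-acid
# residues are anhydro (condensation already applied).
RESIDUES <- list(
  HPO3   = c(H = 1L, P = 1L, O = 3L),
  H2O    = c(H = 2L, O = 1L),
  O1     = c(O = 1L),
  Hex    = c(C = 6L, H = 10L, O = 5L),          # anhydro hexose
  HexNAc = c(C = 8L, H = 13L, N = 1L, O = 5L),  # anhydro N-acetylhexosamine
  NeuAc  = c(C = 11L, H = 17L, N = 1L, O = 8L), # anhydro N-acetylneuraminic acid
  SO3    = c(S = 1L, O = 3L),
  PEA    = c(C = 2L, H = 6L, N = 1L, O = 3L, P = 1L), # phosphoethanolamine (net)
  Eth    = c(C = 2L, H = 5L, N = 1L)            # PA -> PE headgroup delta
)

parse_chain <- function(token, position, name) {
  token <- trimws(token)
  m <- regmatches(token, regexec("^(d|t|P-|O-)?([0-9]+):([0-9]+)$", token))[[1]]
  if (!length(m)) {
    stop(sprintf("cannot parse lipid name %s: bad chain token \"%s\"",
                 dQuote(name), token), call. = FALSE)
  }
  chain <- list(prefix = m[2], carbons = as.integer(m[3]),
                double_bonds = as.integer(m[4]), position = position)
  if (chain$carbons < 2L) {
    stop(sprintf("chain \"%s\" in %s has fewer than 2 carbons", token,
                 dQuote(name)), call. = FALSE)
  }
  if (chain$double_bonds < 0L || chain$double_bonds > chain$carbons / 2) {
    stop(sprintf("chain \"%s\" in %s has an impossible double-bond count",
                 token, dQuote(name)), call. = FALSE)
  }
  chain
}

#' Parse a shorthand lipid name
#'
#' Parses names of the form `CLASS(chain[/chain][(2OH)])`, e.g.
#' `"ST(d18:1/24:0(2OH))"`, `"PE(P-18:0/22:6)"`, `"PE-Cer(36:1)"` or
#' `"LPA(18:0)"`. For sphingolipid classes a single `C:D` spec is interpreted
#' as the total composition of a d-sphingoid species (one double bond on the
#' sphingoid base); a leading chain without the `d` prefix is accepted and
#' treated as the sphingoid base. For the glycerophospholipid classes PA, PE
#' and PI a single chain denotes the lyso species (LPA/LPE/LPI), and a `P-`
#' prefix on the first chain of PE denotes the plasmalogen (vinyl ether,
#' PE-P). A trailing `(2OH)` marks the 2-hydroxylated fatty acyl variant.
#'
#' @param name Shorthand lipid name (character scalar).
#' @return A `lipid_species` object: list with `name` (canonical spelling),
#'   `lipid_class`, `chains`, `total_carbons`, `total_double_bonds`,
#'   `hydroxylated`, `formula` (`element_counts`) and `neutral_mass` (Da).
#' @examples
#' parse_lipid_name("ST(d18:1/24:0)")
#' parse_lipid_name("GM1(d18:1/18:0)")$neutral_mass
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("`name` must be a single character string", call. = FALSE)
  }
  raw <- name
  x <- gsub("\\s+", "", name)
  # the 2-hydroxy tag sits inside the outer parentheses, after the last chain
  hydroxylated <- grepl("\\(2OH\\)", x)
  x <- sub("\\(2OH\\)", "", x)
  m <- regmatches(x, regexec("^([A-Za-z0-9-]+)\\((.+)\\)$", x))[[1]]
  if (!length(m)) {
    stop(sprintf("cannot parse lipid name %s: expected CLASS(chains)",
                 dQuote(raw)), call. = FALSE)
  }
  cls <- m[2]
  inner <- m[3]
  if (cls == "Cer-PE") cls <- "PE-Cer"  # alternative spelling
  tokens <- strsplit(inner, "/", fixed = TRUE)[[1]]
  if (length(tokens) < 1L || length(tokens) > 2L) {
    stop(sprintf("cannot parse lipid name %s: expected 1 or 2 chains",
                 dQuote(raw)), call. = FALSE)
  }
  chains <- lapply(seq_along(tokens), function(i)
    parse_chain(tokens[i], i, raw))

  # plasmalogen: P- prefix on the sn1 chain of PE
  if (chains[[1]]$prefix == "P-") {
    if (cls != "PE") {
      stop(sprintf("P- (plasmalogen) prefix only supported for PE, not %s",
                   cls), call. = FALSE)
    }
    cls <- "PE-P"
  }
  if (!cls %in% LIPID_CLASSES) {
    stop(sprintf("unsupported lipid class \"%s\" in %s (supported: %s)",
                 cls, dQuote(raw), paste(LIPID_CLASSES, collapse = ", ")),
         call. = FALSE)
  }
  # single-chain PA/PE/PI are the lyso species
  if (length(chains) == 1L && cls %in% c("PA", "PE", "PI")) {
    cls <- paste0("L", cls)
  }
  if (length(chains) == 1L && cls == "PE-P") {
    stop(sprintf("plasmalogen %s requires two chains", dQuote(raw)),
         call. = FALSE)
  }
  if (cls %in% c("LPA", "CPA", "LPE", "LPI") && length(chains) != 1L) {
    stop(sprintf("lyso/cyclic species %s must have exactly one chain",
                 dQuote(raw)), call. = FALSE)
  }
  if (hydroxylated && !cls %in% SPHINGO_CLASSES) {
    stop("(2OH) is only supported for sphingolipid classes", call. = FALSE)
  }

  total_c <- sum(vapply(chains, `[[`, integer(1), "carbons"))
  total_d <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  if (cls %in% SPHINGO_CLASSES) {
    if (length(chains) == 1L) {
      # total composition: D includes the sphingoid double bond
      if (total_d < 1L) {
        stop(sprintf("sphingolipid %s must carry at least the sphingoid double bond",
                     dQuote(raw)), call. = FALSE)
      }
    } else if (chains[[1]]$prefix == "") {
      chains[[1]]$prefix <- "d"  # bare first chain taken as the d-sphingoid
    }
  }

  sp <- structure(list(
    name = canonical_name(cls, chains, hydroxylated),
    input_name = raw,
    lipid_class = cls,
    chains = chains,
    total_carbons = total_c,
    total_double_bonds = total_d,
    hydroxylated = hydroxylated
  ), class = "lipid_species")
  sp$formula <- build_formula(sp)
  sp$neutral_mass <- monoisotopic_mass(sp$formula)
  sp
}

canonical_name <- function(cls, chains, hydroxylated) {
  fmt <- vapply(chains, function(ch)
    paste0(ch$prefix, ch$carbons, ":", ch$double_bonds), character(1))
  if (length(fmt) == 2L && hydroxylated) {
    fmt[2] <- paste0(fmt[2], "(2OH)")
    hydroxylated <- FALSE
  }
  out_cls <- if (cls == "PE-P") "PE" else cls
  if (cls == "PE-P" && !startsWith(fmt[1], "P-")) fmt[1] <- paste0("P-", fmt[1])
  paste0(out_cls, "(", paste(fmt, collapse = "/"),
         if (hydroxylated) "(2OH)", ")")
}

# Ceramide backbone with a d-sphingoid base: Cer(total C:D) = C(T) H(2T-2D+1) N O3,
# equivalently Cer(d18:1/X:Y) = C(18+X) H(35+2X-2Y) N O3.
ceramide_formula <- function(total_c, total_d) {
  h <- 2L * total_c - 2L * total_d + 1L
  element_counts(C = total_c, H = h, N = 1L, O = 3L)
}

# Diacyl phosphatidic acid PA(C:D) = C(C+3) H(2C+5-2D) O8 P.
pa_formula <- function(c, d) {
  element_counts(C = c + 3L, H = 2L * c + 5L - 2L * d, O = 8L, P = 1L)
}

# Lyso (monoacyl) LPA(C:D) = C(C+3) H(2C+7-2D) O7 P.
lpa_formula <- function(c, d) {
  element_counts(C = c + 3L, H = 2L * c + 7L - 2L * d, O = 7L, P = 1L)
}

#' Build the molecular formula of a parsed lipid species
#'
#' Applies the class construction rules on top of the ceramide (sphingolipids)
#' or phosphatidic-acid (glycerophospholipids) backbone: CerP = Cer + HPO3;
#' HexCer = Cer + hexose; ST = HexCer + SO3; PE-Cer = Cer + phosphoethanolamine;
#' GM3 = Cer + 2 Hex + NeuAc; GM2 = GM3 + HexNAc; GM1 = GM2 + Hex;
#' PE = PA + C2H5N; PI = PA + Hex(anhydro-inositol); lyso species use the
#' monoacyl backbone; CPA = LPA - H2O; PE-P = PE - O; "(2OH)" adds O.
#'
#' @param species A `lipid_species` (as from [parse_lipid_name()]).
#' @return `element_counts` molecular formula.
#' @export
build_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  cls <- species$lipid_class
  res <- lapply(RESIDUES, function(r) do.call(element_counts, as.list(r)))
  f <-
    if (cls %in% SPHINGO_CLASSES) {
      base <- ceramide_formula(species$total_carbons, species$total_double_bonds)
      switch(cls,
        "Cer"    = base,
        "CerP"   = formula_add(base, res$HPO3),
        "PE-Cer" = formula_add(base, res$PEA),
        "HexCer" = formula_add(base, res$Hex),
        "ST"     = formula_add(formula_add(base, res$Hex), res$SO3),
        "GM3"    = Reduce(formula_add, list(base, res$Hex, res$Hex, res$NeuAc)),
        "GM2"    = Reduce(formula_add, list(base, res$Hex, res$Hex, res$NeuAc,
                                            res$HexNAc)),
        "GM1"    = Reduce(formula_add, list(base, res$Hex, res$Hex, res$Hex,
                                            res$NeuAc, res$HexNAc))
      )
    } else {
      c1 <- species$chains[[1]]
      switch(cls,
        "PA"   = pa_formula(species$total_carbons, species$total_double_bonds),
        "LPA"  = lpa_formula(c1$carbons, c1$double_bonds),
        "CPA"  = formula_subtract(lpa_formula(c1$carbons, c1$double_bonds),
                                  res$H2O),
        "PE"   = formula_add(pa_formula(species$total_carbons,
                                        species$total_double_bonds), res$Eth),
        "LPE"  = formula_add(lpa_formula(c1$carbons, c1$double_bonds), res$Eth),
        "PE-P" = formula_subtract(
                   formula_add(pa_formula(species$total_carbons,
                                          species$total_double_bonds), res$Eth),
                   res$O1),
        "PI"   = formula_add(pa_formula(species$total_carbons,
                                        species$total_double_bonds), res$Hex),
        "LPI"  = formula_add(lpa_formula(c1$carbons, c1$double_bonds), res$Hex)
      )
    }
  if (species$hydroxylated) f <- formula_add(f, res$O1)
  f
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  class %s  %s  %.4f Da\n",
              x$name, x$lipid_class, format(x$formula), x$neutral_mass))
  invisible(x)
}
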