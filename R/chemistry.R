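# Monoisotopic mass arithmetic for peptides, crosslinkers and fragment ions.

# IUPAC monoisotopic atomic masses (Da), >= 5 decimal places.
.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Residue elemental compositions of the 20 proteinogenic amino acids.
.residue_compositions <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Physical constants used throughout the package
#'
#' Monoisotopic constants used for m/z arithmetic and for the precursor
#' isotope-error simulator.
#'
#' @return A named list with elements `proton` (mass of a proton, Da),
#'   `isotope_spacing` (C13-C12 spacing, Da) and `water` (monoisotopic mass
#'   of H2O, Da).
#' @export
#' @examples
#' xl_constants()$proton
xl_constants <- function() {
  list(
    proton = 1.00728,
    isotope_spacing = 1.00335,
    water = unname(2 * .element_masses[["H"]] + .element_masses[["O"]])
  )
}

.proton <- 1.00728
.water <- 2 * 1.0078250319 + 15.9949146221

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named numeric vector or list of non-negative element
#'   counts, e.g. `c(C = 8, H = 10, O = 2)`. Supported elements: C, H, N, O, S.
#' @return Monoisotopic mass in Da (0 for an empty composition).
#' @export
#' @examples
#' composition_mass(c(H = 2, O = 1)) # water, 18.01056
composition_mass <- function(composition) {
  counts <- unlist(composition)
  if (length(counts) == 0) return(0)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition must be a named vector of element counts")
  }
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("element counts must be non-negative")
  sum(counts * .element_masses[names(counts)])
}

# Merge two compositions by summing counts per element.
.merge_compositions <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  elems <- union(names(a), names(b))
  out <- vapply(elems, function(e) {
    sum(a[names(a) == e]) + sum(b[names(b) == e])
  }, numeric(1))
  out
}

#' Crosslinker specification
#'
#' Defines the chemistry of a crosslinking reagent: which residues it reacts
#' with, the mass added when both ends react (bridge), when a single end
#' reacts and the other hydrolyses (monolink), and, for MS-cleavable reagents,
#' the remnant ("stub") compositions left on each peptide after gas-phase
#' cleavage of the spacer.
#'
#' @param name Identifier, e.g. `"DSS"`.
#' @param bridge Elemental composition added when both ends react.
#' @param reactive_residues Character vector of reactive amino-acid letters
#'   (default lysine).
#' @param monolink Composition of the hydrolysed single-ended product.
#'   Defaults to `bridge + H2O`, the standard NHS-ester hydrolysis product.
#' @param stubs Named list of stub compositions for MS-cleavable reagents;
#'   an empty list means non-cleavable. A cleavable reagent needs at least
#'   two stubs.
#' @return An object of class `crosslinker_spec`.
#' @export
#' @examples
#' dss <- crosslinker_spec("DSS", bridge = c(C = 8, H = 10, O = 2))
#' dss$bridge_mass
crosslinker_spec <- function(name, bridge, reactive_residues = "K",
                             monolink = NULL, stubs = list()) {
  bridge <- unlist(bridge)
  bridge_mass <- composition_mass(bridge)
  if (is.null(monolink)) {
    monolink <- .merge_compositions(bridge, c(H = 2, O = 1))
  }
  stubs <- lapply(stubs, unlist)
  if (length(stubs) == 1) {
    stop("a cleavable crosslinker needs at least two stub compositions")
  }
  stub_masses <- vapply(stubs, composition_mass, numeric(1))
  if (any(stub_masses >= bridge_mass + .water)) {
    stop("every stub mass must be smaller than bridge mass + water")
  }
  structure(list(
    name = name,
    reactive_residues = reactive_residues,
    bridge = bridge,
    bridge_mass = bridge_mass,
    monolink = monolink,
    monolink_mass = composition_mass(monolink),
    stubs = stubs,
    stub_masses = stub_masses,
    cleavable = length(stubs) >= 2
  ), class = "crosslinker_spec")
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat(sprintf("<crosslinker %s: bridge %.5f Da, monolink %.5f Da, %s>\n",
              x$name, x$bridge_mass, x$monolink_mass,
              if (x$cleavable) {
                sprintf("cleavable (%d stubs)", length(x$stubs))
              } else "non-cleavable"))
  invisible(x)
}

#' Built-in crosslinker definitions
#'
#' Default chemistries for the common lysine-reactive reagents: DSS and BS3
#' (same C8H10O2 bridge), and the MS-cleavable DSBU and DSSO. All compositions
#' are editable configuration, not fixed constants: pass a YAML file to
#' [load_crosslinkers()] to override or extend them.
#'
#' @return Named list of [crosslinker_spec()] objects.
#' @export
#' @examples
#' names(default_crosslinkers())
#' doublet_deltas(default_crosslinkers()$DSSO)
default_crosslinkers <- function() {
  list(
    DSS = crosslinker_spec("DSS", bridge = c(C = 8, H = 10, O = 2)),
    BS3 = crosslinker_spec("BS3", bridge = c(C = 8, H = 10, O = 2)),
    DSBU = crosslinker_spec(
      "DSBU",
      bridge = c(C = 9, H = 12, N = 2, O = 3),
      stubs = list(
        bu = c(C = 4, H = 7, N = 1, O = 1),
        bu_ur = c(C = 5, H = 5, N = 1, O = 2)
      )
    ),
    DSSO = crosslinker_spec(
      "DSSO",
      bridge = c(C = 6, H = 6, O = 3, S = 1),
      stubs = list(
        alkene = c(C = 3, H = 2, O = 1),
        thiol = c(C = 3, H = 2, O = 1, S = 1)
      )
    )
  )
}

#' Look up a crosslinker by name
#'
#' @param name Crosslinker name (case-insensitive) among the defaults, or a
#'   `crosslinker_spec` which is returned unchanged.
#' @param definitions Optional list of specs to search (default the built-ins).
#' @return A `crosslinker_spec`.
#' @export
crosslinker <- function(name, definitions = default_crosslinkers()) {
  if (inherits(name, "crosslinker_spec")) return(name)
  hit <- match(toupper(name), toupper(names(definitions)))
  if (is.na(hit)) {
    stop("unknown crosslinker '", name, "'; available: ",
         paste(names(definitions), collapse = ", "))
  }
  definitions[[hit]]
}

#' Load crosslinker definitions from a YAML configuration file
#'
#' The file holds a `crosslinkers:` mapping of name to fields
#' `reactive_residues`, `bridge`, optional `monolink` and optional `stubs`,
#' each composition an element-count map. Every composition is validated
#' through [composition_mass()] at load time.
#'
#' @param path Path to a YAML file.
#' @return Named list of [crosslinker_spec()] objects.
#' @export
load_crosslinkers <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- cfg$crosslinkers
  if (is.null(defs)) stop("no 'crosslinkers' section in ", path)
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    crosslinker_spec(
      name = nm,
      bridge = unlist(d$bridge),
      reactive_residues = if (is.null(d$reactive_residues)) "K" else d$reactive_residues,
      monolink = if (is.null(d$monolink)) NULL else unlist(d$monolink),
      stubs = if (is.null(d$stubs)) list() else d$stubs
    )
  })
  names(out) <- names(defs)
  out
}

.residue_masses <- vapply(.residue_compositions, function(comp) {
  sum(unlist(comp) * .element_masses[names(unlist(comp))])
}, numeric(1))

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.residue_masses))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  residues
}

#' Monoisotopic neutral mass of a linear peptide
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @param sequence Peptide sequence over the 20 amino-acid letters.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G") # 75.03203
peptide_mass <- function(sequence) {
  residues <- .check_sequence(sequence)
  sum(.residue_masses[residues]) + .water
}

#' Neutral mass of a crosslinked peptide pair
#'
#' The intact mass measured for a crosslinked moiety: both peptide masses plus
#' the crosslinker bridge.
#'
#' @param seq_a,seq_b Peptide sequences.
#' @param xl A [crosslinker_spec()] or crosslinker name.
#' @return Neutral monoisotopic mass in Da.
#' @export
crosslinked_mass <- function(seq_a, seq_b, xl) {
  xl <- crosslinker(xl)
  peptide_mass(seq_a) + peptide_mass(seq_b) + xl$bridge_mass
}

#' Theoretical b/y fragment ions of a (possibly crosslinked) peptide
#'
#' Generates the b- and y-ion ladder of one peptide. Fragments containing the
#' link site carry extra mass: for a non-cleavable crosslinker the bridge plus
#' the intact partner peptide; for an MS-cleavable crosslinker one ion variant
#' per remnant stub (the partner is lost on spacer cleavage). With
#' `partner_mass = 0` and no crosslinker the plain linear ladder is returned.
#' Setting `partner_mass = xl$monolink_mass - xl$bridge_mass` (i.e. one water)
#' yields the ladder of a monolinked peptide.
#'
#' @param sequence Peptide sequence.
#' @param link_site 1-based residue index of the crosslinked residue
#'   (`NA` or `0` for an unmodified peptide).
#' @param partner_mass Neutral mass added through the link beyond the bridge
#'   (the partner peptide for a crosslink, one water for a monolink).
#' @param xl Optional [crosslinker_spec()]; `NULL` for a plain peptide.
#' @param charges Integer vector of fragment charge states (default 1:2).
#' @return data.frame with columns `ion` ("b"/"y"), `index`, `variant`
#'   (stub name or ""), `charge`, `mz`, `contains_link`.
#' @export
#' @examples
#' fragment_mzs("AKR", link_site = 2, partner_mass = 500,
#'              xl = default_crosslinkers()$DSS, charges = 1)
fragment_mzs <- function(sequence, link_site = NA, partner_mass = 0,
                         xl = NULL, charges = 1:2) {
  if (any(charges < 1)) stop("charges must be >= 1")
  residues <- .check_sequence(sequence)
  n <- length(residues)
  if (n < 2) {
    return(data.frame(ion = character(), index = integer(),
                      variant = character(), charge = integer(),
                      mz = numeric(), contains_link = logical()))
  }
  if (!is.null(xl)) xl <- crosslinker(xl)
  masses <- .residue_masses[residues]
  prefix <- cumsum(masses)            # b_i neutral mass
  suffix <- rev(cumsum(rev(masses)))  # residues i..n
  idx <- seq_len(n - 1)
  b_neutral <- prefix[idx]
  y_neutral <- suffix[idx + 1] + .water  # y_(n-i) for cut after residue i
  has_link <- !is.na(link_site) && link_site >= 1
  b_link <- if (has_link) idx >= link_site else rep(FALSE, n - 1)
  y_link <- if (has_link) idx + 1 <= link_site else rep(FALSE, n - 1)
  # one mass-addition variant per stub for cleavable mode, else a single
  # variant of bridge + partner (0 when no crosslinker)
  if (!is.null(xl) && xl$cleavable) {
    variants <- xl$stub_masses
  } else if (!is.null(xl)) {
    variants <- c(xl$bridge_mass + partner_mass)
    names(variants) <- ""
  } else {
    variants <- c(partner_mass)
    names(variants) <- ""
  }
  out <- vector("list", length(variants) * length(charges))
  k <- 0
  for (v in seq_along(variants)) {
    add <- variants[[v]]
    vname <- names(variants)[v]
    bv <- b_neutral + ifelse(b_link, add, 0)
    yv <- y_neutral + ifelse(y_link, add, 0)
    for (z in charges) {
      k <- k + 1
      out[[k]] <- data.frame(
        ion = rep(c("b", "y"), each = n - 1),
        index = c(idx, n - idx),
        variant = vname,
        charge = as.integer(z),
        mz = c((bv + z * .proton) / z, (yv + z * .proton) / z),
        contains_link = c(b_link, y_link)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Diagnostic doublet mass differences of an MS-cleavable crosslinker
#'
#' MS-cleavable reagents leave one of several remnant stubs on each peptide;
#' the same fragment therefore appears at several masses, and the pairwise
#' stub mass differences are the diagnostic doublet spacings searched for in
#' MS2 spectra.
#'
#' @param xl A cleavable [crosslinker_spec()].
#' @return Numeric vector of all pairwise absolute stub-mass differences,
#'   sorted ascending.
#' @export
#' @examples
#' doublet_deltas(default_crosslinkers()$DSSO) # 31.97207
doublet_deltas <- function(xl) {
  xl <- crosslinker(xl)
  if (!xl$cleavable) stop("no doublets defined: '", xl$name, "' is non-cleavable")
  m <- unname(xl$stub_masses)
  pairs <- utils::combn(length(m), 2)
  sort(abs(m[pairs[1, ]] - m[pairs[2, ]]))
}
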