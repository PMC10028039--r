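# Hairpin PI-polyamide backbones, recognition-motif derivation and
# molecular-formula mass utilities.

# Closed monomer token set. Arms may contain only ring/aliphatic units.
.MONOMERS <- c("Py", "Im", "Beta", "GammaTurn", "AcCap", "CTerm", "Dp",
               "IndoleSecoCBI")
.ARM_MONOMERS <- c("Py", "Im", "Beta")

#' Construct a hairpin polyamide
#'
#' A hairpin pyrrole-imidazole polyamide is represented by its two arms of
#' ring/aliphatic monomers flanking a single gamma (turn) unit, plus an
#' optional N-terminal cap and C-terminal tail (e.g. an indole-seco-CBI
#' alkylating warhead).
#'
#' @param arm1 character vector of monomer codes for the N-terminal arm
#'   (cap excluded), each one of `"Py"`, `"Im"`, `"Beta"`.
#' @param arm2 character vector of monomer codes for the C-terminal arm
#'   (the arm after the gamma turn, tail excluded).
#' @param cap optional cap monomer (`"AcCap"`) or `NULL`.
#' @param tail optional tail monomer (`"Dp"`, `"IndoleSecoCBI"`) or `NULL`.
#' @param name compound label.
#' @return An object of class `hairpin_polyamide`.
#' @export
hairpin_polyamide <- function(arm1, arm2, cap = NULL, tail = NULL,
                              name = NA_character_) {
  arm1 <- as.character(arm1); arm2 <- as.character(arm2)
  bad <- setdiff(c(arm1, arm2), .ARM_MONOMERS)
  if (length(bad))
    stop("arm monomers must be Py/Im/Beta; got: ", paste(bad, collapse = ", "))
  if (!length(arm1) || !length(arm2))
    stop("both arms must contain at least one monomer")
  if (length(arm2) > length(arm1))
    stop("unsupported geometry: arm2 (", length(arm2),
         ") longer than arm1 (", length(arm1), ")")
  if (!is.null(cap) && !identical(cap, "AcCap"))
    stop("cap must be NULL or 'AcCap'")
  if (!is.null(tail) && !tail %in% c("Dp", "IndoleSecoCBI"))
    stop("tail must be NULL, 'Dp' or 'IndoleSecoCBI'")
  structure(list(name = name, arm1 = arm1, arm2 = arm2, cap = cap,
                 tail = tail),
            class = "hairpin_polyamide")
}

#' @export
print.hairpin_polyamide <- function(x, ...) {
  cat("<hairpin_polyamide>", if (!is.na(x$name)) x$name else "", "\n")
  cat("  ", format_backbone(x), "\n", sep = "")
  if (!is.null(x$tail)) cat("  tail:", x$tail, "\n")
  invisible(x)
}

# token table used by the backbone tokenizer; beta/gamma accept plain-text
# aliases because configs cannot always carry Greek letters
.BETA_ALIASES  <- c("β", "b", "beta")
.GAMMA_ALIASES <- c("γ", "g", "gamma")

.tokenize_segment <- function(seg, offset) {
  # greedy left-to-right ring tokenizer within one hyphen-delimited segment
  out <- character(0)
  i <- 1L
  n <- nchar(seg)
  while (i <= n) {
    rest <- substr(seg, i, n)
    hit <- NA_character_
    for (tok in c("beta", "Py", "Im", "β", "b", "B")) {
      if (tolower(substr(rest, 1L, nchar(tok))) == tolower(tok)) {
        hit <- tok; break
      }
    }
    if (is.na(hit)) {
      stop("parse error: unknown token starting at '",
           substr(rest, 1L, min(4L, nchar(rest))), "' (offset ",
           offset + i - 1L, ")")
    }
    out <- c(out, if (tolower(hit) %in% c("beta", "b", "β")) "Beta"
             else if (tolower(hit) == "py") "Py" else "Im")
    i <- i + nchar(hit)
  }
  out
}

#' Parse a hairpin polyamide backbone string
#'
#' Accepts the conventional hyphen-delimited backbone notation, e.g.
#' `"Ac-NH-PyPyPyPyβPyPyPy-γ-ImImβImImPy-COOH"`. The single
#' gamma token splits the two arms; `Ac-NH` records an acetyl cap and
#' `COOH` the free acid terminus. `β` may be written `b` or `beta`
#' and `γ` as `g` or `gamma` (case-insensitive).
#'
#' @param text backbone string.
#' @param tail optional tail conjugate, `"IndoleSecoCBI"` or `"Dp"`.
#' @param name compound label carried on the result.
#' @return A [hairpin_polyamide()] object.
#' @examples
#' parse_backbone("Py-g-Py")
#' @export
parse_backbone <- function(text, tail = NULL, name = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  segs <- strsplit(text, "-", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  cap <- NULL
  # "Ac-NH" splits into two segments
  if (length(segs) >= 2L && tolower(segs[1]) == "ac" &&
      tolower(segs[2]) == "nh") {
    cap <- "AcCap"
    segs <- segs[-(1:2)]
  }
  if (length(segs) && tolower(segs[length(segs)]) %in%
        c("indolesecocbi", "indole-seco-cbi", "dp")) {
    tl <- tolower(segs[length(segs)])
    tail <- if (tl == "dp") "Dp" else "IndoleSecoCBI"
    segs <- segs[-length(segs)]
  }
  if (length(segs) && tolower(segs[length(segs)]) == "cooh")
    segs <- segs[-length(segs)]
  is_gamma <- tolower(segs) %in% tolower(.GAMMA_ALIASES)
  if (sum(is_gamma) != 1L)
    stop("structural error: backbone must contain exactly one γ turn, ",
         "found ", sum(is_gamma))
  gi <- which(is_gamma)
  arm1_segs <- segs[seq_len(gi - 1L)]
  arm2_segs <- segs[seq.int(gi + 1L, length(segs))[seq_len(length(segs) - gi)]]
  if (!length(arm1_segs) || !length(arm2_segs))
    stop("structural error: empty arm around the γ turn")
  off <- 0L
  arm1 <- unlist(lapply(arm1_segs, function(s) {
    r <- .tokenize_segment(s, off); off <<- off + nchar(s); r
  }))
  arm2 <- unlist(lapply(arm2_segs, function(s) {
    r <- .tokenize_segment(s, off); off <<- off + nchar(s); r
  }))
  hairpin_polyamide(arm1, arm2, cap = cap, tail = tail, name = name)
}

#' Canonical backbone string of a hairpin polyamide
#'
#' Inverse of [parse_backbone()]: `parse_backbone(format_backbone(pa))`
#' reconstructs `pa` (the tail is carried in the string when present).
#'
#' @param pa a [hairpin_polyamide()].
#' @return A single backbone string using `β`/`γ` glyphs.
#' @export
format_backbone <- function(pa) {
  stopifnot(inherits(pa, "hairpin_polyamide"))
  glyph <- function(m) c(Py = "Py", Im = "Im", Beta = "β")[m]
  paste0(if (!is.null(pa$cap)) "Ac-NH-" else "",
         paste(glyph(pa$arm1), collapse = ""),
         "-γ-",
         paste(glyph(pa$arm2), collapse = ""),
         "-COOH",
         if (!is.null(pa$tail)) paste0("-", pa$tail) else "")
}

#' Construct a degenerate DNA recognition motif
#'
#' @param iupac motif string over the IUPAC nucleotide alphabet
#'   (`ACGTRYSWKMBDHVN`); `W` (A or T) is the typical degeneracy of
#'   polyamide recognition.
#' @param alkylation_index 0-based position of the adenine alkylated by a
#'   seco-CBI warhead, or `NULL`.
#' @return An object of class `degenerate_motif`.
#' @export
degenerate_motif <- function(iupac, alkylation_index = NULL) {
  stopifnot(is.character(iupac), length(iupac) == 1L)
  iupac <- toupper(iupac)
  if (nchar(iupac) < 2L) stop("motif must have length >= 2")
  chars <- strsplit(iupac, "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ""))
  if (!is.null(alkylation_index)) {
    alkylation_index <- as.integer(alkylation_index)
    if (alkylation_index < 0L || alkylation_index >= nchar(iupac))
      stop("alkylation_index out of range")
    if (chars[alkylation_index + 1L] != "A")
      stop("alkylated base must be A, found ", chars[alkylation_index + 1L])
  }
  structure(list(iupac = iupac, alkylation_index = alkylation_index),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif>", x$iupac,
      if (!is.null(x$alkylation_index))
        paste0("(alkylation at ", x$alkylation_index, ")"), "\n")
  invisible(x)
}

# Ring-pair recognition code: row = ring on the motif strand (arm2 side),
# column = stacked partner ring (arm1 side). Im reads G regardless of
# partner; Py or beta opposite Im reads C; all-Py/beta pairs read W.
.PAIR_RULE <- matrix(
  c("W", "C", "W",   # Py / (Py, Im, Beta)
    "G", "G", "G",   # Im / (Py, Im, Beta)
    "W", "C", "W"),  # Beta / (Py, Im, Beta)
  nrow = 3, byrow = TRUE,
  dimnames = list(c("Py", "Im", "Beta"), c("Py", "Im", "Beta")))

#' Derive the duplex recognition motif of a hairpin polyamide
#'
#' Applies minor-groove pairing rules to the stacked ring pairs of a hairpin:
#' turn-proximal rings pair first (arm2 position k stacks on arm1 position
#' n1 + 1 - k), and the motif is written 5'->3' on the strand read by the
#' C-terminal arm. The gamma turn contributes one 5'-terminal W; unpaired
#' arm1 overhang rings each read W; an indole-seco-CBI tail extends the
#' 3' end so the motif terminates in `WWA`, the terminal adenine being the
#' alkylation site (the indole linker's two W positions coincide with
#' overhang positions when an overhang is present).
#'
#' @param pa a [hairpin_polyamide()].
#' @return A [degenerate_motif()]; `alkylation_index` is set when the tail
#'   is `IndoleSecoCBI`.
#' @examples
#' derive_motif(parse_backbone("Py-g-Py"))  # "WW"
#' @export
derive_motif <- function(pa) {
  stopifnot(inherits(pa, "hairpin_polyamide"))
  n1 <- length(pa$arm1); n2 <- length(pa$arm2)
  if (n2 > n1)
    stop("unsupported geometry: arm2 longer than arm1")
  pairs <- vapply(seq_len(n2), function(k)
    .PAIR_RULE[pa$arm2[k], pa$arm1[n1 + 1L - k]], character(1))
  overhang <- n1 - n2
  chars <- c("W", pairs, rep("W", overhang))
  alk <- NULL
  if (identical(pa$tail, "IndoleSecoCBI")) {
    chars <- c(chars, rep("W", max(0L, 2L - overhang)), "A")
    alk <- length(chars) - 1L
  }
  degenerate_motif(paste(chars, collapse = ""), alkylation_index = alk)
}

# ---- molecular formulae ----------------------------------------------------

# Monoisotopic (most abundant isotope) atomic masses, IUPAC 2021 values.
.MONO_MASS <- c(
  H = 1.00782503207, B = 11.00930536, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, F = 18.99840316, Na = 22.98976928, Mg = 23.985041697,
  Al = 26.98153853, Si = 27.97692653465, P = 30.97376199842,
  S = 31.9720711744, Cl = 34.968852682, K = 38.9637064864,
  Ca = 39.962590863, Mn = 54.93804391, Fe = 55.93493633, Co = 58.93319429,
  Ni = 57.93534241, Cu = 62.92959772, Zn = 63.92914201, As = 74.92159457,
  Se = 79.9165218, Br = 78.9183376, I = 126.9044719, Li = 7.0160034366,
  Sn = 119.90220163, Ag = 106.9050916, Pt = 194.9647917, Au = 196.96656879,
  Hg = 201.97064340, Pb = 207.9766525)

.PROTON_MASS <- 1.007276

#' Parse a Hill-notation molecular formula
#'
#' @param text formula string, element symbols each followed by an optional
#'   integer count (omitted count = 1), e.g. `"C102H105ClN34O18"`.
#' @return An object of class `molecular_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    stop("malformed formula: ", text)
  sym <- sub("[0-9]*$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  bad <- setdiff(sym, names(.MONO_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(cnt < 1L)) stop("zero element count in formula: ", text)
  counts <- tapply(cnt, sym, sum)
  structure(as.integer(counts), names = names(counts),
            class = "molecular_formula")
}

#' Canonical Hill-order formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (all alphabetical when no carbon). `parse_formula(format_formula(f))`
#' round-trips.
#'
#' @param f a [parse_formula()] result.
#' @return A formula string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  sym <- names(f)
  ord <- if ("C" %in% sym) {
    c("C", "H"[("H" %in% sym)], sort(setdiff(sym, c("C", "H"))))
  } else sort(sym)
  paste0(ord, ifelse(f[ord] > 1L, f[ord], ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#' Full precision is returned; use [round_half_up()] with 2 decimals for
#' display alongside typical LC-MS reporting.
#'
#' @param f a [parse_formula()] result (a bare named count vector is also
#'   accepted).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(f) {
  sym <- names(f)
  bad <- setdiff(sym, names(.MONO_MASS))
  if (length(bad))
    stop("element(s) missing from mass table: ", paste(bad, collapse = ", "))
  sum(as.numeric(f) * .MONO_MASS[sym])
}

#' m/z of the protonated ion [M+H]+
#'
#' @inheritParams monoisotopic_mass
#' @return Monoisotopic mass plus the proton mass (1.007276 Da).
#' @export
protonated_mz <- function(f) monoisotopic_mass(f) + .PROTON_MASS

#' Round half away from zero
#'
#' Decimal display rounding (half-up), as used for 2-decimal mass reporting;
#' base `round()` rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Load a compound registry
#'
#' Reads a TSV with columns `name`, `motif`, `backbone`, `tail`; each row
#' supplies either a direct IUPAC motif or a backbone string from which the
#' motif is derived. A bundled registry with the three screen compounds
#' (KR12, CCC-002, CCC-003) ships in `inst/extdata/compounds.tsv`.
#'
#' @param path TSV path; default the bundled registry.
#' @return Named list of [degenerate_motif()] objects.
#' @export
load_compound_registry <- function(path = system.file("extdata",
                                                      "compounds.tsv",
                                                      package = "piscreen")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("name", "motif", "backbone", "tail")
  if (!all(need %in% names(tab)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tail <- if (is.na(tab$tail[i])) NULL else tab$tail[i]
    if (!is.na(tab$backbone[i]) && nzchar(tab$backbone[i])) {
      derive_motif(parse_backbone(tab$backbone[i], tail = tail,
                                  name = tab$name[i]))
    } else {
      iupac <- tab$motif[i]
      alk <- NULL
      if (identical(tail, "IndoleSecoCBI") &&
          substr(iupac, nchar(iupac), nchar(iupac)) == "A")
        alk <- nchar(iupac) - 1L
      degenerate_motif(iupac, alkylation_index = alk)
    }
  })
  names(out) <- tab$name
  out
}
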