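#' Construct a structure model
#'
#' A `structure_model` is the package's in-memory representation of a protein
#' structure: a table of atoms with coordinates in nanometres, a table of
#' residues, and the ordered chain list. It is deliberately minimal — enough
#' to drive covariance/ellipsoid fits and dipole sums.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_index`, `x`, `y`, `z` (coordinates in nm).
#' @param residues data.frame with columns `index`, `name` (3-letter code),
#'   `chain`, `number` (current residue number, author numbering on read).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, residues) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  need_a <- c("serial", "name", "element", "res_index", "x", "y", "z")
  need_r <- c("index", "name", "chain", "number")
  if (!all(need_a %in% names(atoms)))
    stop("atoms table must have columns: ", paste(need_a, collapse = ", "))
  if (!all(need_r %in% names(residues)))
    stop("residues table must have columns: ", paste(need_r, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (!all(atoms$res_index %in% residues$index))
    stop("atom res_index values reference missing residues")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  # each chain's residues must appear in order
  for (ch in unique(residues$chain)) {
    idx <- residues$index[residues$chain == ch]
    if (is.unsorted(idx)) stop("residue indices within chain ", ch, " not ordered")
  }
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  structure(
    list(atoms = atoms, residues = residues,
         chains = unique(residues$chain)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues,", length(x$chains), "chain(s) [",
      paste(x$chains, collapse = " "), "]\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param model a `structure_model`
#' @return numeric matrix, one row per atom, columns x/y/z in nm
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Read a protein structure from PDB or GRO
#'
#' PDB files are parsed with bio3d (first model, alternate locations other
#' than A dropped) and coordinates converted from angstrom to nm. GRO files
#' (already in nm) are parsed directly. Only ATOM records are kept for PDB:
#' waters, ions and other heteroatoms are excluded from the model.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "gro".
#' @param on_empty what to do if no protein atoms remain: "error" (default)
#'   or "warn" (returns NULL with a warning).
#' @return a `structure_model`, or NULL when `on_empty = "warn"` fires.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           on_empty = c("error", "warn")) {
  format <- match.arg(format)
  on_empty <- match.arg(on_empty)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (format == "pdb") .read_pdb_model(path, on_empty) else .read_gro_model(path)
}

.read_pdb_model <- function(path, on_empty) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ,
           drop = FALSE]
  if (nrow(at) == 0L) {
    msg <- paste0("no protein ATOM records in ", path,
                  " (heteroatoms/waters only?)")
    if (on_empty == "error") stop(msg)
    warning(msg)
    return(NULL)
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1L, 1L)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  res_key <- paste(chain, at$resno, at$insert, sep = "|")
  res_index <- match(res_key, unique(res_key))
  first <- !duplicated(res_key)
  residues <- data.frame(
    index = seq_len(sum(first)),
    name = at$resid[first],
    chain = chain[first],
    number = at$resno[first],
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(elem),
    res_index = res_index,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,   # angstrom -> nm
    stringsAsFactors = FALSE
  )
  structure_model(atoms, residues)
}

.read_gro_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("unparseable GRO file: too short")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || length(lines) < n + 3L)
    stop("unparseable GRO file: bad atom count line")
  body <- lines[3:(2 + n)]
  resno <- as.integer(substr(body, 1, 5))
  resnm <- trimws(substr(body, 6, 10))
  atnm  <- trimws(substr(body, 11, 15))
  serial <- as.integer(substr(body, 16, 20))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  if (anyNA(c(x, y, z))) stop("unparseable GRO coordinates")
  res_key <- paste(resno, resnm)
  res_index <- match(res_key, unique(res_key))
  first <- !duplicated(res_key)
  residues <- data.frame(index = seq_len(sum(first)), name = toupper(resnm[first]),
                         chain = "A", number = resno[first],
                         stringsAsFactors = FALSE)
  atoms <- data.frame(serial = serial, name = atnm,
                      element = substr(atnm, 1, 1), res_index = res_index,
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  structure_model(atoms, residues)
}

#' Write a structure model to a PDB file
#'
#' Coordinates are converted from nm to angstrom. Residue numbers written are
#' the model's current numbers (gapless if [renumber_gapless()] was applied).
#'
#' @param model a `structure_model`
#' @param path output path
#' @return the path, invisibly
#' @export
write_structure_pdb <- function(model, path) {
  res <- model$residues[model$atoms$res_index, ]
  xyz <- as.vector(t(coords(model) * 10))  # nm -> angstrom
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = res$number, resid = res$name, chain = res$chain,
                   eleno = model$atoms$serial, elety = model$atoms$name,
                   elesy = model$atoms$element)
  invisible(path)
}

#' Renumber residues gaplessly
#'
#' Crystallographic tubulin structures (e.g. 1JFF, 1TUB) contain numbering
#' gaps where residues are unresolved; the gapless convention closes them so
#' each chain is numbered consecutively from its first residue. A residue
#' following a 2-gap after number 44 becomes 45; the residue after an 8-gap
#' following 360 becomes 361.
#'
#' @param model a `structure_model`
#' @return the model with consecutive residue numbers per chain; the
#'   old-to-new mapping is attached as attribute `renumber_map` (a data.frame
#'   with columns chain, author_number, number).
#' @export
renumber_gapless <- function(model) {
  res <- model$residues
  new_number <- res$number
  for (ch in model$chains) {
    sel <- which(res$chain == ch)
    nums <- res$number[sel]
    if (anyDuplicated(nums))
      stop("duplicate author residue numbers in chain ", ch)
    new_number[sel] <- nums[1L] + seq_along(sel) - 1L
  }
  map <- data.frame(chain = res$chain, author_number = res$number,
                    number = new_number, stringsAsFactors = FALSE)
  res$number <- new_number
  out <- structure_model(model$atoms, res)
  attr(out, "renumber_map") <- map
  out
}

#' Write a gapless-renumbering map to CSV
#' @param model a model returned by [renumber_gapless()]
#' @param path output CSV path
#' @export
write_renumber_map <- function(model, path) {
  map <- attr(model, "renumber_map")
  if (is.null(map)) stop("model has no renumber_map; run renumber_gapless() first")
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Charges

#' Construct a charge assignment
#'
#' @param charges numeric vector of charges in elementary charge units;
#'   per-atom when `mode = "partial"`, per-residue when `mode = "formal"`.
#' @param mode "partial" (force-field atomic charges) or "formal"
#'   (integer side-chain charges at a given pH).
#' @param pH assumed pH (recorded only).
#' @return object of class `charge_assignment` with fields `charges`, `mode`,
#'   `total`, `pH`.
#' @export
charge_assignment <- function(charges, mode = c("partial", "formal"), pH = 7) {
  mode <- match.arg(mode)
  charges <- as.numeric(charges)
  if (anyNA(charges)) stop("non-numeric charge entries")
  total <- sum(charges)
  structure(list(charges = charges, mode = mode, total = total, pH = pH),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat("charge_assignment:", length(x$charges), "entries, mode", x$mode,
      ", total", format(x$total), "e (pH", x$pH, ")\n")
  invisible(x)
}

# side-chain formal charges at pH 7
.formal_rule <- c(ASP = -1, GLU = -1, LYS = +1, ARG = +1, HIS = 0)

#' Assign formal per-residue charges at pH 7
#'
#' Default rule: Asp/Glu −1, Lys/Arg +1, His neutral (the common pH-7
#' convention; configurable), every other standard residue 0. Non-standard
#' residue names get 0 with a warning. Terminal charges (+1 at each chain
#' N-terminus, −1 at each C-terminus) are off by default, appropriate for
#' sub-chain selections such as C-terminal tails.
#'
#' @param model a `structure_model`
#' @param his_charge charge assigned to histidine (default 0)
#' @param termini if TRUE, add +1 to each chain's first residue and −1 to its
#'   last residue
#' @return a `charge_assignment` with `mode = "formal"` (one entry per residue)
#' @export
assign_formal_charges <- function(model, his_charge = 0, termini = FALSE) {
  rule <- .formal_rule
  rule["HIS"] <- his_charge
  res <- model$residues
  q <- unname(rule[res$name])
  standard <- c(names(rule), "ALA", "ASN", "CYS", "GLN", "GLY", "ILE", "LEU",
                "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  unknown <- setdiff(unique(res$name[is.na(q)]), standard)
  if (length(unknown) > 0L)
    warning("non-standard residues assigned charge 0: ",
            paste(unknown, collapse = ", "))
  q[is.na(q)] <- 0
  if (termini) {
    for (ch in model$chains) {
      sel <- which(res$chain == ch)
      q[sel[1L]] <- q[sel[1L]] + 1
      q[sel[length(sel)]] <- q[sel[length(sel)]] - 1
    }
  }
  charge_assignment(q, mode = "formal", pH = 7)
}

#' Load per-atom (or per-residue) charges from a CSV table
#'
#' Accepts two schemas: `atom_serial,charge` (per-atom partial charges,
#' aligned to the model's atom order) or `chain,resnum,charge` (per-residue
#' charges, mode "formal").
#'
#' @param path CSV file
#' @param model the `structure_model` the charges belong to
#' @return a `charge_assignment`
#' @export
load_partial_charges <- function(path, model) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("atom_serial", "charge") %in% names(tab))) {
    if (!is.numeric(tab$charge)) stop("non-numeric charge column")
    idx <- match(model$atoms$serial, tab$atom_serial)
    if (anyNA(idx)) {
      missing <- model$atoms$serial[is.na(idx)]
      stop("charge table missing atoms with serial: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    }
    charge_assignment(tab$charge[idx], mode = "partial")
  } else if (all(c("chain", "resnum", "charge") %in% names(tab))) {
    if (!is.numeric(tab$charge)) stop("non-numeric charge column")
    key_model <- paste(model$residues$chain, model$residues$number)
    idx <- match(key_model, paste(tab$chain, tab$resnum))
    if (anyNA(idx)) {
      missing <- key_model[is.na(idx)]
      stop("charge table missing residues: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    }
    charge_assignment(tab$charge[idx], mode = "formal")
  } else {
    stop("unrecognised charge table schema; expected columns ",
         "(atom_serial,charge) or (chain,resnum,charge)")
  }
}

# ---------------------------------------------------------------------------
# Residue selections

#' Construct a residue selection
#'
#' An ordered set of (chain, residue-number) pairs with a label, validated
#' against a model. Residue numbers refer to the model's current numbering
#' (gapless if renumbered).
#'
#' @param model a `structure_model`
#' @param chain chain id(s), recycled against `number`
#' @param number residue number(s)
#' @param label selection label (e.g. "beta-CTT", "paclitaxel-site")
#' @return object of class `residue_selection`: data.frame (chain, number)
#'   with a `label` attribute
#' @export
residue_selection <- function(model, chain, number, label = "") {
  sel <- data.frame(chain = rep_len(as.character(chain), length(number)),
                    number = as.integer(number), stringsAsFactors = FALSE)
  if (anyDuplicated(sel)) stop("duplicate residues in selection '", label, "'")
  key_model <- paste(model$residues$chain, model$residues$number)
  missing <- !(paste(sel$chain, sel$number) %in% key_model)
  if (any(missing))
    stop("selection '", label, "' names residues absent from model: ",
         paste(paste(sel$chain[missing], sel$number[missing]), collapse = ", "))
  attr(sel, "label") <- label
  class(sel) <- c("residue_selection", "data.frame")
  sel
}

#' Residue table indices covered by a selection
#' @param model a `structure_model`
#' @param selection a `residue_selection`, or NULL for all residues
#' @return integer vector of residue indices
#' @export
selection_residue_indices <- function(model, selection = NULL) {
  if (is.null(selection)) return(model$residues$index)
  idx <- match(paste(selection$chain, selection$number),
               paste(model$residues$chain, model$residues$number))
  if (anyNA(idx)) stop("selection members missing from model")
  model$residues$index[idx]
}

#' Atom row indices covered by a selection
#' @inheritParams selection_residue_indices
#' @return integer vector of atom row indices
#' @export
selection_atom_indices <- function(model, selection = NULL) {
  if (is.null(selection)) return(seq_len(nrow(model$atoms)))
  which(model$atoms$res_index %in% selection_residue_indices(model, selection))
}

#' Select a chain's C-terminal tail
#'
#' The C-terminal tail (CTT) is the short, acidic, unstructured terminal
#' segment of each tubulin monomer: by convention the last 16 residues of the
#' alpha chain and the last 20 of the beta chain. If `length` is omitted it
#' defaults from the chain id ("A"/"alpha" -> 16, "B"/"beta" -> 20).
#'
#' @param model a `structure_model`
#' @param chain chain id
#' @param length number of terminal residues; see default rule above
#' @return a `residue_selection` labelled `"<chain>-CTT"`
#' @export
select_ctt <- function(model, chain, length = NULL) {
  if (is.null(length)) {
    length <- switch(tolower(chain), a = , alpha = 16L, b = , beta = 20L,
                     stop("no default CTT length for chain '", chain,
                          "'; supply length"))
  }
  sel <- which(model$residues$chain == chain)
  if (base::length(sel) == 0L) stop("chain not found: ", chain)
  if (base::length(sel) < length)
    stop("chain ", chain, " has ", base::length(sel),
         " residues, fewer than requested CTT length ", length)
  tail_idx <- sel[(base::length(sel) - length + 1L):base::length(sel)]
  residue_selection(model, model$residues$chain[tail_idx],
                    model$residues$number[tail_idx],
                    label = paste0(chain, "-CTT"))
}

#' One-letter sequence of a selection
#' @param model a `structure_model`
#' @param selection a `residue_selection` (NULL = all residues)
#' @return character scalar, one-letter amino-acid codes ("X" for unknown)
#' @export
selection_sequence <- function(model, selection = NULL) {
  idx <- selection_residue_indices(model, selection)
  aa3 <- model$residues$name[match(idx, model$residues$index)]
  aa1 <- bio3d::aa321(aa3)
  aa1[is.na(aa1)] <- "X"
  paste(aa1, collapse = "")
}

#' Load binding-site definitions
#'
#' Reads a JSON config mapping site names to lists of (chain, resnum)
#' entries. The packaged default (`inst/extdata/binding_sites.json`) carries
#' the tubulin sites tracked by this package: the GTP hydrolysis exemplar
#' residue (alpha-Asp 251), the longitudinal-contact exemplar (beta-Arg 391),
#' and the paclitaxel, colchicine and vinca drug-binding sites. Residue
#' numbers use the gapless convention.
#'
#' @param path JSON config; default = packaged site table
#' @param model optional `structure_model`; when given, each site is bound
#'   (validated) against it and missing residues raise an error
#' @return named list of `residue_selection` objects (unvalidated plain
#'   data.frames when `model` is NULL)
#' @export
load_site_definitions <- function(path = NULL, model = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "binding_sites.json", package = "tubupol")
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(names(cfg), function(nm) {
    entries <- cfg[[nm]]
    chain <- vapply(entries, function(e) as.character(e$chain), "")
    number <- vapply(entries, function(e) as.integer(e$resnum), 1L)
    if (is.null(model)) {
      sel <- data.frame(chain = chain, number = number, stringsAsFactors = FALSE)
      attr(sel, "label") <- nm
      class(sel) <- c("residue_selection", "data.frame")
      sel
    } else {
      residue_selection(model, chain, number, label = nm)
    }
  })
  names(out) <- names(cfg)
  out
}
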