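#' Read a protein charge/dipole record table
#'
#' CSV schema: `id, chain, charge_e, dipole_debye, set` — one row per
#' protein chain, where `set` labels the population ("family" for the
#' protein family under study, "background" for the reference set of unique
#' PDB chains).
#'
#' @param path CSV file
#' @return data.frame of protein records
#' @export
read_protein_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "chain", "charge_e", "dipole_debye", "set")
  if (!all(need %in% names(tab)))
    stop("record table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(tab$charge_e) || !is.numeric(tab$dipole_debye))
    stop("charge_e and dipole_debye must be numeric")
  bad <- !is.finite(tab$charge_e) | !is.finite(tab$dipole_debye)
  if (any(bad)) stop(sum(bad), " records with non-finite values")
  tab
}

#' Summarise a charge or dipole distribution per population
#'
#' @param records data.frame from [read_protein_records()] (or any frame
#'   with the same columns)
#' @param variable "charge_e" or "dipole_debye"
#' @param by grouping column (default "set"); use NA to summarise all
#'   records as one set
#' @return data.frame with one row per group: n, mean, median, q25, q75,
#'   min, max
#' @export
summarize_set <- function(records, variable = c("charge_e", "dipole_debye"),
                          by = "set") {
  variable <- match.arg(variable)
  if (nrow(records) == 0L) stop("empty record set")
  groups <- if (is.na(by)) list(all = records[[variable]])
            else split(records[[variable]], records[[by]])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) == 0L) stop("empty group: ", g)
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(set = g, variable = variable, n = length(v), mean = mean(v),
               median = qs[2], q25 = qs[1], q75 = qs[3],
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of a protein's charge carried by its C-terminal tail
#'
#' Defined with absolute values, |ctt_charge| / |total_charge|, so a tail
#' whose charge opposes the body's still counts its share of charge
#' magnitude. Across the tubulin family this fraction averages roughly a
#' third, which is what makes the short acidic tail the prime target of an
#' applied field.
#'
#' @param total_charge whole-protein charge in e (non-zero)
#' @param ctt_charge tail charge in e
#' @return non-negative fraction (1 when the tail carries all the charge)
#' @export
ctt_charge_fraction <- function(total_charge, ctt_charge) {
  if (any(total_charge == 0))
    stop("charge fraction undefined for zero total charge")
  abs(ctt_charge) / abs(total_charge)
}
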