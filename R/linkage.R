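# Allele assignment against a reference library, multi-locus haplotype
# tabulation and marker linkage percentages.  Allele labels are opaque
# strings; TE presence/absence loci use "present"/"absent" and
# unresolvable loci "GAP".

#' Assign an allele label by comparison to a reference library
#'
#' An exact full-length match returns that label with status `exact`;
#' otherwise the best-identity library entry with identity of at least
#' `min_identity` over coverage of at least `min_coverage` is returned
#' with status `novel`; anything else (including queries that are more
#' than 10% `N`) is `GAP`.
#'
#' @param query DNA text.
#' @param library named character vector of allele sequences for one
#'   locus.
#' @param min_identity identity threshold for novel-allele assignment
#'   (default 0.99).
#' @param min_coverage length-coverage threshold
#'   `min(nq,nl)/max(nq,nl)` (default 0.9).
#' @return List with `allele`, `status` (`exact`/`novel`/`GAP`) and
#'   `identity`.
#' @export
assign_allele <- function(query, library, min_identity = 0.99,
                          min_coverage = 0.9) {
  if (length(library) == 0) stop("empty allele library")
  nq <- nchar(query)
  n_frac <- lengths(regmatches(query, gregexpr("N", query))) / max(nq, 1)
  if (nq == 0 || n_frac > 0.1)
    return(list(allele = "GAP", status = "GAP", identity = NA_real_))
  hit <- which(library == query)
  if (length(hit))
    return(list(allele = names(library)[hit[1]], status = "exact",
                identity = 1))
  ident <- vapply(library, function(ref) {
    nl <- nchar(ref)
    if (nl == nq) {
      a <- charToRaw(query); b <- charToRaw(ref)
      skip <- a == charToRaw("N") | b == charToRaw("N")
      comp <- sum(!skip)
      if (comp == 0) return(0)
      sum(a[!skip] == b[!skip]) / comp
    } else {
      al <- align_global(query, ref)
      m <- sum(al$ops$len[al$ops$op == "M"])
      cols <- sum(al$ops$len[al$ops$op %in% c("M", "X")])
      if (cols == 0) 0 else m / cols
    }
  }, numeric(1))
  cover <- vapply(library, function(ref)
    min(nq, nchar(ref)) / max(nq, nchar(ref)), numeric(1))
  ok <- ident >= min_identity & cover >= min_coverage
  if (any(ok)) {
    best <- which(ok)[which.max(ident[ok])]
    return(list(allele = names(library)[best], status = "novel",
                identity = unname(ident[best])))
  }
  list(allele = "GAP", status = "GAP",
       identity = if (length(ident)) unname(max(ident)) else NA_real_)
}

# long (haplotype, locus, allele) records -> wide label matrix
records_wide <- function(records, loci) {
  stopifnot(all(c("haplotype", "locus", "allele") %in% names(records)))
  haps <- unique(records$haplotype)
  wide <- matrix(NA_character_, length(haps), length(loci),
                 dimnames = list(haps, loci))
  sel <- records$locus %in% loci
  wide[cbind(match(records$haplotype[sel], haps),
             match(records$locus[sel], loci))] <- records$allele[sel]
  wide
}

#' Tabulate distinct multi-locus haplotypes
#'
#' Groups records by their allele-label tuple over the selected loci
#' ("GAP" is an ordinary label); records missing any selected locus
#' are dropped and reported.
#'
#' @param records data frame in long form: `haplotype`, `locus`,
#'   `allele`.
#' @param loci character vector of loci defining the haplotype.
#' @return List with `table` (data frame: one column per locus,
#'   `count`; sorted by count descending then lexicographically),
#'   `total` (records tabulated), `dropped` (haplotype ids missing a
#'   locus).
#' @export
tabulate_haplotypes <- function(records, loci) {
  if (length(loci) == 0) stop("no loci selected")
  wide <- records_wide(records, loci)
  complete <- !apply(is.na(wide), 1, any)
  dropped <- rownames(wide)[!complete]
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) == 0)
    return(list(table = data.frame(), total = 0L, dropped = dropped))
  key <- apply(wide, 1, paste, collapse = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- loci
  out$count <- as.integer(tab)
  o <- do.call(order, c(list(-out$count), out[loci]))
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, total = sum(out$count), dropped = dropped)
}

#' Linkage percentages between two markers
#'
#' Contingency counts of marker B values within each marker A value,
#' with row percentages.  Records with "GAP" at either marker are
#' excluded and reported.
#'
#' @param records long-form records (see [tabulate_haplotypes()]).
#' @param marker_a,marker_b locus names.
#' @return List with `table` (data frame `a_value`, `b_value`,
#'   `count`, `percent` of the `a_value` rows) and `excluded`
#'   (haplotype ids with GAP or missing values).
#' @export
linkage_percentages <- function(records, marker_a, marker_b) {
  wide <- records_wide(records, c(marker_a, marker_b))
  bad <- apply(wide, 1, function(x) any(is.na(x) | x == "GAP"))
  excluded <- rownames(wide)[bad]
  wide <- wide[!bad, , drop = FALSE]
  if (nrow(wide) == 0)
    return(list(table = data.frame(a_value = character(),
                                   b_value = character(),
                                   count = integer(),
                                   percent = numeric()),
                excluded = excluded))
  tab <- as.data.frame(table(a_value = wide[, 1], b_value = wide[, 2]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  row_tot <- tapply(tab$count, tab$a_value, sum)
  tab$percent <- 100 * tab$count / as.numeric(row_tot[tab$a_value])
  tab <- tab[order(tab$a_value, tab$b_value), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, excluded = excluded)
}
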