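#' Read a nearest-neighbor energy parameter table
#'
#' The parameter file is a TSV with columns `category`, `key1`, `key2`, `dg`
#' (kcal/mol). Categories: `stack` (key1 = outer pair, key2 = inner pair),
#' `hairpin` / `bulge` / `internal` (key1 = loop size), the internal-loop
#' asymmetry entries (`internal` with key1 `asym_per_nt` / `asym_max`),
#' `multiloop` (key1 in offset/branch/unpaired) and `init` (key1 `duplex`).
#'
#' @param path path to the TSV file.
#' @return an [EnergyModel-class].
#' @export
readEnergyModel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("category", "key1", "key2", "dg")
  if (!all(need %in% names(tab)))
    stop("energy parameter file must have columns ",
         paste(need, collapse = ", "))
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- tab[tab$category == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  stack[cbind(st$key1, st$key2)] <- st$dg
  if (anyNA(stack)) stop("incomplete stack table")
  sizeTab <- function(cat, exclude = character(0)) {
    x <- tab[tab$category == cat & !(tab$key1 %in% exclude), ]
    v <- x$dg
    names(v) <- x$key1
    v[order(as.integer(names(v)))]
  }
  asym <- tab[tab$category == "internal" &
              tab$key1 %in% c("asym_per_nt", "asym_max"), ]
  ml <- tab[tab$category == "multiloop", ]
  mlv <- setNames(ml$dg, ml$key1)
  init <- tab[tab$category == "init" & tab$key1 == "duplex", "dg"]
  new("EnergyModel",
      stack = stack,
      hairpin = sizeTab("hairpin"),
      bulge = sizeTab("bulge"),
      internal = sizeTab("internal", exclude = c("asym_per_nt", "asym_max")),
      asymPerNt = unname(asym$dg[asym$key1 == "asym_per_nt"]),
      asymMax = unname(asym$dg[asym$key1 == "asym_max"]),
      mlOffset = unname(mlv["offset"]), mlBranch = unname(mlv["branch"]),
      mlUnpaired = unname(mlv["unpaired"]),
      duplexInit = if (length(init)) init else 4.1,
      maxLoop = 30L)
}

#' The packaged default energy model
#'
#' Turner-style stacking energies (Watson--Crick and GU wobble) with
#' size-dependent loop penalties; see [readEnergyModel()] for the file
#' schema. The table ships in `inst/extdata/energy_params.tsv` and can be
#' edited or replaced via the `energyParamPath` configuration field.
#'
#' @return an [EnergyModel-class].
#' @examples
#' em <- defaultEnergyModel()
#' em@stack["CG", "CG"]
#' @export
defaultEnergyModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- readEnergyModel(system.file("extdata", "energy_params.tsv",
                                            package = "milrscan",
                                            mustWork = TRUE))
    cache
  }
})

# Jacobson-Stockmayer extrapolation of a tabulated loop-penalty vector out
# to loops of size n (RT = 0.616 kcal/mol at 37C).
extendLoopTable <- function(tab, n) {
  sizes <- as.integer(names(tab))
  lo <- min(sizes)
  hi <- max(sizes)
  out <- rep(NA_real_, max(n, hi))
  out[sizes] <- unname(tab)
  if (max(n, hi) > hi) {
    extra <- (hi + 1L):max(n, hi)
    out[extra] <- tab[[as.character(hi)]] +
      1.75 * 0.616 * log(extra / hi)
  }
  out[is.na(out)] <- Inf  # sizes below the tabulated minimum are forbidden
  out
}
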