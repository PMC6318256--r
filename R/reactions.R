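#' Pseudo-first-order transformation reaction table
#'
#' Reactions are rows of a data frame with columns `parent`, `product`
#' (a chemical id or the sink `"other"`), `kind` (`"photo"`, `"bio"` or
#' `"deconjugation"`) and `half_life_h` (hours at the reference temperature).
#' Several rows with the same parent and kind are competing first-order
#' channels; their half-lives combine harmonically into the parent's total
#' half-life for that kind.
#'
#' @param parent,product,kind,half_life_h Vectors of equal length (recycled by
#'   `data.frame`); see Details.
#' @return A validated `data.frame` of class `reaction_table`.
#' @export
reaction_table <- function(parent, product, kind, half_life_h) {
  tab <- data.frame(parent = as.character(parent),
                    product = as.character(product),
                    kind = as.character(kind),
                    half_life_h = as.numeric(half_life_h),
                    stringsAsFactors = FALSE)
  bad <- !tab$kind %in% c("photo", "bio", "deconjugation")
  if (any(bad)) stop("unknown reaction kind: ",
                     paste(unique(tab$kind[bad]), collapse = ", "))
  if (any(!is.finite(tab$half_life_h) | tab$half_life_h <= 0))
    stop("all half-lives must be positive and finite")
  if (any(tab$parent == tab$product))
    stop("a reaction product must differ from its parent")
  class(tab) <- c("reaction_table", "data.frame")
  tab
}

#' Packaged transformation reaction half-lives
#'
#' Loads the packaged photo- and biotransformation half-life table for the
#' three parent pharmaceuticals and their transformation products. CPAB, the
#' one product with no literature degradation half-life, carries its parent's
#' total rates (4.0 h photo, 9.825 h bio).
#'
#' @param path Optional path to an alternative CSV with columns
#'   `parent,product,kind,half_life_h`.
#' @return A `reaction_table`.
#' @export
default_reactions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reaction_half_lives.csv",
                        package = "lakefate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  reaction_table(tab$parent, tab$product, tab$kind, tab$half_life_h)
}

#' First-order rate constant from a half-life
#'
#' `k = ln(2) / t_half` per hour. `Inf` is accepted as a "no reaction"
#' sentinel and maps to 0.
#'
#' @param t_half Half-life, hours; positive (possibly `Inf`).
#' @return Rate constant, 1/h.
#' @export
rate_from_half_life <- function(t_half) {
  if (any(!is.na(t_half) & t_half <= 0))
    stop("half-life must be positive")
  ifelse(is.infinite(t_half), 0, log(2) / t_half)
}

#' Combine competing first-order half-lives
#'
#' Harmonic combination `[sum(1/t_i)]^-1`: the total half-life of a parent
#' subject to several competing first-order channels. An empty input returns
#' `Inf` ("no reaction").
#'
#' @param t_list Numeric vector of half-lives, hours, all positive.
#' @return Combined half-life, hours.
#' @export
combine_half_lives <- function(t_list) {
  t_list <- t_list[!is.na(t_list)]
  if (length(t_list) == 0L) return(Inf)
  if (any(t_list <= 0)) stop("half-lives must be positive")
  1 / sum(1 / t_list)
}

#' Transformation product yield
#'
#' Fraction of the parent's total degradation that forms a given product:
#' `yield = k_formation / k_total = t_total / t_formation`. (Stated in words
#' as a half-life ratio, the relation only stays within [0, 1] as the rate
#' ratio; the reciprocal reading would exceed 1 and is rejected.)
#'
#' @param formation_half_life Half-life of the formation channel, hours.
#' @param total_half_life Combined half-life of all channels, hours.
#' @return Yield fraction in [0, 1].
#' @export
tp_yield <- function(formation_half_life, total_half_life) {
  if (any(formation_half_life < total_half_life))
    stop("formation half-life cannot be shorter than the total half-life ",
         "(yield would exceed 1)")
  total_half_life / formation_half_life
}

#' Depth attenuation of photolysis
#'
#' Band lookup for the fraction of the surface photolysis rate available to a
#' water layer: 100% for 0-0.1 m, 10% for 0.1-1 m, 1% for 1-5 m and none
#' below 5 m. A layer spanning bands takes the band of its top boundary (the
#' packaged geometries align layer and band boundaries exactly; a warning is
#' emitted otherwise).
#'
#' @param depth_top,depth_bottom Layer bounds, m, `0 <= top < bottom`.
#' @return Multiplier in [0, 1].
#' @export
photolysis_depth_multiplier <- function(depth_top, depth_bottom) {
  if (depth_top < 0 || depth_bottom <= depth_top)
    stop("need 0 <= depth_top < depth_bottom")
  bands <- c(0, 0.1, 1, 5)
  mult <- c(1, 0.1, 0.01, 0)
  band_top <- findInterval(depth_top, bands)
  if (findInterval(depth_bottom - 1e-12, bands) != band_top)
    warning("layer ", depth_top, "-", depth_bottom,
            " m spans photolysis bands; using the top-boundary band")
  mult[band_top]
}

#' Temperature correction of a reaction rate
#'
#' Exponential-in-temperature correction `k * exp(gamma * (t - t_ref))`. The
#' default `gamma = ln(2)/10` halves the rate per 10 degree C drop.
#'
#' @param k Rate constant at `t_ref`, 1/h.
#' @param t Ambient temperature, degrees C.
#' @param t_ref Reference temperature, degrees C.
#' @param gamma Exponential coefficient, 1/degree C.
#' @return Corrected rate constant, 1/h.
#' @export
temperature_correct_rate <- function(k, t, t_ref = 25, gamma = log(2) / 10) {
  if (any(k < 0)) stop("rate constants must be >= 0")
  k * exp(gamma * (t - t_ref))
}

#' Group chemicals into reaction chains
#'
#' Partitions a chemical set into chains closed under the parent->product
#' relation (the sink `"other"` excluded): chemicals that never react and are
#' never formed stand alone. Each chain is solved as one linear system by the
#' engine.
#'
#' @param chemical_ids Character vector of chemical ids in the scenario.
#' @param reactions A [reaction_table()].
#' @return List of character vectors (disjoint, covering all ids).
#' @export
reaction_chains <- function(chemical_ids, reactions) {
  # simple union-find over chemical ids
  up <- seq_along(chemical_ids)
  root <- function(i) { while (up[i] != i) i <- up[i]; i }
  rel <- reactions[reactions$product != "other", , drop = FALSE]
  for (r in seq_len(nrow(rel))) {
    i <- match(rel$parent[r], chemical_ids)
    j <- match(rel$product[r], chemical_ids)
    if (is.na(i) || is.na(j)) next
    ri <- root(i); rj <- root(j)
    if (ri != rj) up[rj] <- ri
  }
  roots <- vapply(seq_along(chemical_ids), root, integer(1))
  unname(lapply(split(chemical_ids, roots), identity))
}

# Per-parent, per-kind reaction summary: total half-life and yields.
# Returns a list keyed "<parent>|<kind>" with elements
# total_half_life, products (ids), yields (same order), sink_yield.
reaction_scheme <- function(reactions) {
  key <- paste(reactions$parent, reactions$kind, sep = "|")
  out <- lapply(split(seq_len(nrow(reactions)), key), function(idx) {
    rows <- reactions[idx, , drop = FALSE]
    total <- combine_half_lives(rows$half_life_h)
    is_prod <- rows$product != "other"
    yields <- tp_yield(rows$half_life_h[is_prod], total)
    list(parent = rows$parent[1], kind = rows$kind[1],
         total_half_life = total,
         products = rows$product[is_prod],
         yields = yields,
         sink_yield = 1 - sum(yields))
  })
  out
}
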