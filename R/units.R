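#' Convert between coalescent time units
#'
#' Linear conversion between the ms time scale (units of 4N0 generations)
#' and generations in units of N0 or Ne. Both populations share the same
#' constant size, so Ne is identified with N0 and that conversion is the
#' identity. The deep-divergence join time `-ej 10` is 40 N0 generations;
#' the recent one, `-ej 0.01`, is 0.04 N0 generations.
#'
#' @param value Non-negative time value(s).
#' @param from,to Units: one of `"4N0"`, `"N0"`, `"Ne"` (the suffixed
#'   forms `"4N0_generations"` etc. are also accepted).
#' @return Converted value(s).
#' @export
#' @examples
#' convert_time(10, "4N0", "N0")    # 40
#' convert_time(0.01, "4N0", "N0")  # 0.04
#' convert_time(6, "Ne", "4N0")     # 1.5
convert_time <- function(value, from, to) {
  if (any(value < 0)) stop("time values must be non-negative")
  f <- unit_factor(from)
  t <- unit_factor(to)
  value * f / t
}

unit_factor <- function(unit) {
  u <- sub("_generations$", "", as.character(unit)[1L])
  switch(u,
         "4N0" = 4,
         "N0" = 1,
         "Ne" = 1,
         stop("unknown time unit '", unit,
              "'; expected one of 4N0, N0, Ne"))
}
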