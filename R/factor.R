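# Internal factor algebra over discrete variables.
#
# A factor is a non-negative table over a set of named discrete variables,
# stored as a flat numeric vector in column-major order with the FIRST
# variable varying fastest (R array convention). A factor with zero
# variables is a scalar (length-1 value vector).

new_factor <- function(vars, states, values) {
  states <- as.list(states)
  names(states) <- vars
  structure(list(vars = vars, states = states, values = as.numeric(values)),
            class = "bbn_factor")
}

.fcard <- function(f) vapply(f$states, length, integer(1L), USE.NAMES = FALSE)

# 1-based linear index from a matrix of 1-based assignments (first var fastest)
.lindex <- function(assn, card) {
  if (length(card) == 0L) return(rep.int(1L, nrow(assn)))
  stride <- cumprod(c(1, card[-length(card)]))
  as.integer((assn - 1L) %*% stride) + 1L
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0L)
    return(new_factor(f2$vars, f2$states, f1$values * f2$values))
  if (length(f2$vars) == 0L)
    return(new_factor(f1$vars, f1$states, f2$values * f1$values))
  vars <- union(f1$vars, f2$vars)
  states <- c(f1$states, f2$states[setdiff(f2$vars, f1$vars)])[vars]
  card <- vapply(states, length, integer(1L), USE.NAMES = FALSE)
  assn <- arrayInd(seq_len(prod(card)), card)
  i1 <- .lindex(assn[, match(f1$vars, vars), drop = FALSE], .fcard(f1))
  i2 <- .lindex(assn[, match(f2$vars, vars), drop = FALSE], .fcard(f2))
  new_factor(vars, states, f1$values[i1] * f2$values[i2])
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  card <- .fcard(f)
  if (length(card) == 1L)
    return(new_factor(character(0L), list(), sum(f$values)))
  a <- array(f$values, dim = card)
  a <- aperm(a, c(seq_along(card)[-i], i))
  dim(a) <- c(prod(card[-i]), card[i])
  new_factor(f$vars[-i], f$states[-i], rowSums(a))
}

# condition on var = state and drop the variable
factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  s <- match(state, f$states[[i]])
  if (is.na(s))
    stop(sprintf("state '%s' is not a state of '%s'", state, var), call. = FALSE)
  card <- .fcard(f)
  assn <- arrayInd(seq_len(prod(card)), card)
  keep <- assn[, i] == s
  new_factor(f$vars[-i], f$states[-i], f$values[keep])
}

# permute a factor's variables into the given order
factor_permute <- function(f, vars) {
  if (identical(f$vars, vars)) return(f)
  perm <- match(vars, f$vars)
  stopifnot(!anyNA(perm), length(perm) == length(f$vars))
  a <- array(f$values, dim = .fcard(f))
  a <- aperm(a, perm)
  new_factor(vars, f$states[perm], as.numeric(a))
}
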