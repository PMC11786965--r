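## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic, order-independent combination of integer seed components,
## kept inside the 32-bit signed range R requires of set.seed().
deriveSeed <- function(master, ...) {
    parts <- c(as.numeric(master), as.numeric(unlist(list(...))))
    primes <- c(1, 7919, 104729, 1299709, 15485863)
    s <- sum(parts * primes[seq_along(parts)]) %% 2147483629
    as.integer(s)
}
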