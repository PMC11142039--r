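mesh: ...................................................

══ DONE ════════════════════════════════════════════════════════════════════════
## mesh done in 0.8482504 secs
forward: ...1.......2...3.....................

══ Failed ══════════════════════════════════════════════════════════════════════
── 1. Failure ('test-forward.R:18:3'): impressed dipole field and potential matc
impressed_potential(dp, rbind(v)) (`actual`) not equal to -impressed_potential(dp, rbind(c(v[1], v[2], -v[3]))) (`expected`).

`names(actual)` is a character vector ('v')
`names(expected)` is absent

── 2. Failure ('test-forward.R:84:5'): near-field analytic triangle integrals ma
a$I0 (`actual`) not equal to q$I0 (`expected`).

actual != expected but don't know how to show the difference

── 3. Failure ('test-forward.R:84:5'): near-field analytic triangle integrals ma
a$I0 (`actual`) not equal to q$I0 (`expected`).

  `actual`: 0.019516
`expected`: 0.019517

══ DONE ════════════════════════════════════════════════════════════════════════
## forward done in 7.6452 secs
amr: ........................

══ DONE ════════════════════════════════════════════════════════════════════════
## amr done in 2.389095 secs
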