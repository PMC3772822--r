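#!/usr/bin/env python
"""Regenerate tests/testthat/pmf-oracle.tsv.

Exact big-rational binomial point-mass values C(n,k) p^k (1-p)^(n-k),
computed with fractions.Fraction and rendered to 17 significant digits.
Grid: all k for n <= 12; representative and extreme k for larger n up to
500; p in {1/200, 1/20} (0.5% and 5%).
"""
from fractions import Fraction
from math import comb

def pmf(n, k, p):
    return comb(n, k) * p**k * (1 - p) ** (n - k)

def fmt(fr):
    """Scientific notation with 17 significant digits, exact rounding."""
    if fr == 0:
        return "0"
    e = 0
    while Fraction(10) ** e > fr:
        e -= 1
    while Fraction(10) ** (e + 1) <= fr:
        e += 1
    mant = round(fr / Fraction(10) ** e * 10 ** 16)
    return f"{mant}e{e - 16}"

rows = []
for p, plab in [(Fraction(1, 200), "0.005"), (Fraction(1, 20), "0.05")]:
    for n in range(1, 13):
        for k in range(0, n + 1):
            rows.append((n, k, plab, pmf(n, k, p)))
    for n in [50, 100, 200, 350, 500]:
        ks = sorted({0, 1, 2, 3, 5, 10, n // 4, n // 2, n - 1, n})
        for k in ks:
            rows.append((n, k, plab, pmf(n, k, p)))

with open("tests/testthat/pmf-oracle.tsv", "w") as fh:
    fh.write("n\tk\tp\tpmf\n")
    for n, k, plab, fr in rows:
        fh.write(f"{n}\t{k}\t{plab}\t{fmt(fr)}\n")
print(f"wrote {len(rows)} rows")
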