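phrase,symbol
up to,<=
at least,>=
at most,<=
no more than,<=
no less than,>=
no fewer than,>=
or higher,>=
or more,>=
or greater,>=
or above,>=
or older,>=
or less,<=
or lower,<=
or fewer,<=
or below,<=
or younger,<=
less than,<
fewer than,<
lower than,<
more than,>
greater than,>
higher than,>
older than,>
younger than,<
over,>
under,<
above,>
below,<
exceeding,>
minimum of,>=
maximum of,<=
equal to,=
≥,>=
≤,<=
>=,>=
<=,<=
<>,<>
>,>
<,<
=,=
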