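%
1	ppron
2	i
3	we
4	you
5	shehe
6	they
10	affect
11	posemo
12	negemo
13	anx
14	anger
15	sad
20	social
21	family
22	friend
30	cogproc
31	insight
32	cause
40	percept
41	see
42	hear
43	feel
50	bio
51	body
52	health
53	ingest
60	drives
61	affiliation
62	achieve
63	power
70	relativ
71	motion
72	space
73	time
80	focuspast
81	focuspresent
82	focusfuture
90	work
91	money
92	death
%
i	1	2
me	2
my	2
mine	2
i'll	2	82
we	3
our	3
us	3
you	4
your	4
she	5
he	5
his	5
her	5
they	6
them	6
their	6
happy	11
good	11
love*	11
hope*	11
nice	11
worr*	13
afraid	13
nervous	13
angr*	10	12	14
hate*	14
rage	14
mad	14
sad*	15
cry*	15
grief	15
hopeless	15
talk*	20
people	20
who	20
family	20	21
mom	21
dad	21
brother	21
friend*	20	22
buddy	22
think*	31
know	31
realiz*	31
understand	31
because	32
why	32
reason*	32
should	30
maybe	30
see	41
saw	41
look*	41
hear*	42
listen*	42
feel*	43
touch	43
body	51
head	51
sleep*	51
tired	51
health*	52
sick	52
pain*	52
ill	52
clinic*	52
eat*	53
food	53
drink*	53
together	61
belong*	61
achiev*	62
fail*	62
success*	62
goal*	62
win	62
control*	63
power*	63
force	63
go	71
went	71
walk*	71
move*	71
run*	71
in	72
out	72
up	72
down	72
here	72
there	72
today	73	81
soon	73
never	73
always	73
hour*	73
day*	73
was	80
were	80
did	80
had	80
ago	80
is	81
am	81
are	81
now	81
will	82
gonna	82
future	82
tomorrow	82
work*	90
job*	90
school	90
money	91
cash	91
pay*	91
death*	92
dead	92
die*	92
suicid*	92
kill*	92
alone	15	20
lonel*	15	20
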