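# French stopword list (function words); one entry per line.
a
à
ai
aie
aies
ait
alors
après
as
assez
au
aucun
aucune
aujourd
aussi
autre
autres
aux
avaient
avais
avait
avant
avec
avez
aviez
avions
avoir
avons
ayant
c
ça
car
ce
ceci
cela
celle
celles
celui
ces
cet
cette
ceux
chaque
chez
comme
comment
d
dans
de
déjà
depuis
des
donc
dont
du
elle
elles
en
encore
enfin
entre
es
est
et
étaient
étais
était
étant
été
êtes
étiez
étions
être
eu
eux
fais
faisait
fait
faites
faut
fois
font
il
ils
j
jamais
je
juste
l
la
là
le
les
leur
leurs
lors
lui
m
ma
mais
me
même
mes
moi
moins
mon
n
ne
ni
non
nos
notre
nous
on
ont
or
ou
où
par
parce
pas
pendant
peu
peut
plus
pour
pourquoi
puis
qu
quand
que
quel
quelle
quelles
quelque
quelques
quels
qui
quoi
rien
s
sa
sans
se
sera
serait
ses
si
sinon
soi
soit
sommes
son
sont
sous
suis
sur
t
ta
tes
toi
ton
toujours
tous
tout
toute
toutes
très
trop
tu
un
une
va
vais
vers
voici
voilà
vont
vos
votre
vous
y
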