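# Synthetic word-frequency list (token<TAB>count), Brown-corpus-like magnitudes.
# Hand-assembled for simulation; not the Brown corpus itself.
THE	69971
OF	36410
AND	28854
TO	26154
A	23363
IN	21345
THAT	10594
IS	10102
WAS	9815
HE	9542
FOR	9489
IT	8760
WITH	7290
AS	7250
HIS	6997
ON	6742
BE	6377
AT	5377
BY	5307
I	5180
THIS	5146
HAD	5133
NOT	4610
ARE	4394
BUT	4381
FROM	4370
OR	4207
HAVE	3941
AN	3748
THEY	3620
WHICH	3562
ONE	3292
YOU	3286
WERE	3284
HER	3037
ALL	3001
SHE	2859
THERE	2724
WOULD	2714
THEIR	2670
WE	2653
HIM	2619
BEEN	2472
HAS	2439
WHEN	2331
WHO	2252
WILL	2245
MORE	2216
NO	2201
IF	2199
OUT	2096
SO	1985
SAID	1961
WHAT	1908
UP	1895
ITS	1858
ABOUT	1815
INTO	1791
THAN	1789
THEM	1789
CAN	1772
ONLY	1747
OTHER	1702
NEW	1635
SOME	1617
COULD	1601
TIME	1598
THESE	1573
TWO	1412
MAY	1402
THEN	1380
DO	1363
FIRST	1361
ANY	1345
MY	1319
NOW	1314
SUCH	1303
LIKE	1290
OUR	1252
OVER	1237
MAN	1207
ME	1181
EVEN	1170
MOST	1160
MADE	1125
AFTER	1070
ALSO	1069
DID	1044
MANY	1030
BEFORE	1016
MUST	1013
THROUGH	969
BACK	966
YEARS	950
WHERE	938
MUCH	937
YOUR	923
WAY	909
WELL	897
DOWN	895
SHOULD	888
BECAUSE	883
EACH	877
JUST	872
THOSE	850
PEOPLE	847
MR	839
HOW	836
TOO	833
LITTLE	831
STATE	807
GOOD	806
VERY	796
MAKE	794
WORLD	787
STILL	782
OWN	772
SEE	772
MEN	763
WORK	760
LONG	755
GET	749
HERE	750
BETWEEN	730
BOTH	730
LIFE	715
BEING	713
UNDER	707
NEVER	698
DAY	687
SAME	686
ANOTHER	683
KNOW	683
WHILE	680
LAST	676
MIGHT	672
US	672
GREAT	665
OLD	661
YEAR	658
OFF	639
COME	630
SINCE	628
AGAINST	626
GO	626
CAME	622
RIGHT	613
USED	612
TAKE	611
THREE	610
STATES	571
HIMSELF	567
FEW	563
HOUSE	561
USE	561
DURING	559
WITHOUT	553
AGAIN	552
PLACE	550
AMERICAN	530
AROUND	525
HOWEVER	518
HOME	509
SMALL	508
FOUND	505
MRS	505
THOUGHT	501
WENT	497
SAY	493
PART	489
ONCE	482
GENERAL	482
HIGH	478
UPON	475
SCHOOL	473
EVERY	468
DONT	467
DOES	462
GOT	458
UNITED	455
LEFT	452
NUMBER	448
COURSE	444
WAR	438
UNTIL	437
ALWAYS	432
AWAY	428
SOMETHING	424
FACT	421
THOUGH	419
WATER	418
LESS	415
PUBLIC	415
PUT	412
THINK	411
ALMOST	407
HAND	405
ENOUGH	398
FAR	398
TOOK	391
HEAD	389
YET	386
GOVERNMENT	383
SYSTEM	381
BETTER	380
SET	379
TOLD	377
NOTHING	373
NIGHT	371
END	369
WHY	368
CALLED	361
DIDNT	359
EYES	358
FIND	355
GOING	351
LOOK	348
ASKED	346
LATER	345
KNEW	338
POINT	337
NEXT	330
PROGRAM	328
CITY	323
BUSINESS	320
GIVE	318
GROUP	318
TOWARD	316
YOUNG	313
DAYS	312
LET	308
ROOM	308
WITHIN	305
CHILDREN	302
SIDE	300
SOCIAL	300
GIVEN	298
ORDER	296
PRESENT	294
SEVERAL	294
NATIONAL	293
SECOND	292
POSSIBLE	289
RATHER	288
PER	287
FACE	286
AMONG	284
FORM	284
IMPORTANT	281
OFTEN	281
THINGS	279
LOOKED	275
EARLY	274
WHITE	273
CASE	271
BECOME	269
LARGE	268
NEED	265
BIG	263
FOUR	262
FELT	259
ALONG	257
BEST	257
CHURCH	255
EVER	255
LEAST	254
POWER	254
DEVELOPMENT	253
LIGHT	253
THING	252
FAMILY	250
INTEREST	250
SEEMED	250
WANT	249
TODAY	246
MEMBERS	245
MIND	244
COUNTRY	243
AREA	242
OTHERS	241
DONE	240
TURNED	240
ALTHOUGH	239
OPEN	238
GOD	237
SERVICE	236
CERTAIN	235
KIND	234
PROBLEM	234
BEGAN	233
DIFFERENT	231
DOOR	231
THUS	231
HELP	230
MEANS	230
SENSE	227
WHOLE	226
MATTER	225
PERHAPS	224
ITSELF	223
TIMES	222
HUMAN	221
LAW	221
LINE	221
ABOVE	220
NAME	219
EXAMPLE	218
ACTION	217
COMPANY	217
HANDS	217
LOCAL	216
SHOW	216
BODY	215
FIVE	213
HISTORY	212
WHOSE	211
QUICK	212
QUICKLY	188
QUIET	179
QUITE	281
QUESTION	257
QUESTIONS	168
QUEEN	94
BROWN	176
BROUGHT	255
BROAD	70
BROKE	58
BROTHER	108
FOX	96
FOOD	147
FOOT	110
FORCE	230
FOREIGN	93
FOREST	66
FORGET	49
FORWARD	86
FREE	260
FRONT	221
FULL	230
FURTHER	218
CAR	274
CARE	162
CARD	26
CART	10
CARRIED	142
CAKE	32
CASES	145
CAUSE	130
CENTER	178
CENTURY	130
CHANGE	240
JUMP	22
JUMPS	9
JUMPED	44
LAZY	17
DOG	147
DOGS	42
OVERALL	14
EOF
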